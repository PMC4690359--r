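Place the published study's supplementary data files here (they are not
redistributable with the package) to enable the full 65-taxon analysis and
the corresponding acceptance tests:

  matrix.tnt        the character matrix (TNT xread or NEXUS)
  ages.csv          taxon,fad_oldest,fad_youngest   (Ma, oldest >= youngest)
  areas.csv         taxon,area                      (six continental areas)
  constraints.json  [{"mode":"enforce","taxa":[...]}, ...] alternative-placement
                    constraint sets for the step-cost experiments
  groups.json       {"neornithischia":[...],"cerapoda":[...],"parksosauridae":[...]}

Then reinstall the package; see ?study_data_paths.
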