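#' @useDynLib stratphylo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Cell encoding: observed cells are bitmasks over states 0..9 (bit i set <=>
# state i present), so "0" = 1L, "1" = 2L, polymorphic {0,1} = 3L.
# MISSING_CELL and INAP_CELL are sentinels; both score as "any state" but are
# kept distinct for round-tripping and reporting.
MISSING_CELL <- -1L
INAP_CELL <- -2L
MAX_STATES <- 10L

#' Continental areas used for the geographic character
#'
#' The six-continent area universe for ancestral-area reconstruction
#' (Antarctica is absent because no terminal taxon occurs there).
#' @export
CONTINENTS <- c("South America", "Africa", "Asia", "North America",
                "Europe", "Australia")

states_to_mask <- function(states) {
  stopifnot(all(states >= 0L & states < MAX_STATES))
  as.integer(sum(bitwShiftL(1L, unique(as.integer(states)))))
}

mask_to_states <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(MAX_STATES - 1L))) != 0L) - 1L
}

#' Construct a morphological character matrix
#'
#' Builds a `morph_matrix`: an ordered set of taxa scored for discrete,
#' unordered characters with states `0`--`9`.  Cells may be observed (a
#' non-empty state set; the only polymorphism supported by the file formats
#' is `{0,1}`, written `"a"`), missing (`"?"`), or inapplicable (`"-"`).
#' Missing and inapplicable cells are stored distinctly but both behave as
#' "any state" in parsimony scoring.
#'
#' @param cells integer matrix of encoded cells (rows = taxa); ordinarily
#'   produced by [parse_morph_matrix()] or [simulate_characters()].
#' @param taxa character vector of unique taxon labels, one per row.
#' @return an object of class `morph_matrix`.
#' @seealso [parse_morph_matrix()], [write_morph_matrix()]
#' @export
morph_matrix <- function(cells, taxa) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (length(taxa) != nrow(cells))
    stop("number of taxon labels (", length(taxa),
         ") does not match number of rows (", nrow(cells), ")")
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  bad <- cells == 0L | cells < INAP_CELL | cells >= bitwShiftL(1L, MAX_STATES)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid cell encoding at taxon ", taxa[idx[1L]],
         ", character ", idx[2L])
  }
  rownames(cells) <- taxa
  colnames(cells) <- NULL
  structure(list(taxa = as.character(taxa), cells = cells),
            class = "morph_matrix")
}

#' @export
print.morph_matrix <- function(x, ...) {
  cat("Morphological character matrix: ", n_taxa(x), " taxa x ",
      n_char(x), " characters\n", sep = "")
  nm <- sum(x$cells == MISSING_CELL)
  ni <- sum(x$cells == INAP_CELL)
  np <- sum(x$cells > 0L & bitwAnd(x$cells, x$cells - 1L) != 0L)
  tot <- length(x$cells)
  cat(sprintf("  missing %.1f%%, inapplicable %.1f%%, polymorphic %.1f%%\n",
              100 * nm / tot, 100 * ni / tot, 100 * np / tot))
  invisible(x)
}

#' @rdname morph_matrix
#' @param x a `morph_matrix`.
#' @export
n_taxa <- function(x) length(x$taxa)

#' @rdname morph_matrix
#' @export
n_char <- function(x) ncol(x$cells)

#' Observed state universe of each character
#'
#' @param x a `morph_matrix`.
#' @return list (length `n_char(x)`) of sorted integer vectors: the states
#'   observed in at least one scorable cell of that character.
#' @export
state_universe <- function(x) {
  lapply(seq_len(n_char(x)), function(j) {
    m <- x$cells[, j]
    m <- m[m > 0L]
    if (!length(m)) return(integer())
    mask <- Reduce(bitwOr, m)
    mask_to_states(mask)
  })
}

symbol_to_cell <- function(sym) {
  if (sym %in% as.character(0:9)) return(states_to_mask(as.integer(sym)))
  switch(sym,
         "a" = 3L,          # polymorphic {0,1}
         "?" = MISSING_CELL,
         "-" = INAP_CELL,
         "−" = INAP_CELL,  # Unicode minus, as in published supplements
         NULL)
}

cell_to_symbol <- function(cell) {
  if (cell == MISSING_CELL) return("?")
  if (cell == INAP_CELL) return("-")
  st <- mask_to_states(cell)
  if (length(st) == 1L) return(as.character(st))
  if (identical(st, c(0L, 1L))) return("a")
  stop("cell with states {", paste(st, collapse = ","),
       "} has no file symbol; only the polymorphism {0,1} (\"a\") is writable")
}

decode_row <- function(string, taxon) {
  syms <- strsplit(string, "")[[1L]]
  cells <- vapply(seq_along(syms), function(i) {
    v <- symbol_to_cell(syms[i])
    if (is.null(v))
      stop("unknown symbol \"", syms[i], "\" at taxon ", taxon,
           ", character ", i, call. = FALSE)
    v
  }, integer(1L))
  cells
}

# Tokenize respecting single-quoted labels; semicolons become tokens.
nexus_tokens <- function(text) {
  text <- gsub(";", " ; ", text, fixed = TRUE)
  m <- gregexpr("'[^']*'|\\[[^]]*\\]|[^\\s\\[']+", text, perl = TRUE)
  toks <- regmatches(text, m)[[1L]]
  toks <- toks[!startsWith(toks, "[")]          # bracket comments
  gsub("^'|'$", "", toks)
}

#' Parse a TNT or NEXUS character matrix
#'
#' Reads a discrete matrix from a TNT `xread` block or a NEXUS
#' `DATA`/`CHARACTERS` block (`DATATYPE=STANDARD`).  The symbol map follows
#' the convention of published ornithischian matrices: digits are single
#' states, `"a"` is the polymorphism `{0,1}`, `"?"` is missing, and `"-"`
#' (ASCII hyphen or Unicode minus) is inapplicable.  Any other symbol is a
#' parse error naming the symbol and its position; row lengths that
#' disagree with the declared dimensions are an error naming the taxon.
#' Interleaved matrices (taxon names repeated across blocks) are supported
#' in both dialects.
#'
#' @param file path to a matrix file, or `NULL` if `text` is given.
#' @param text matrix file content as a single string or character vector
#'   of lines.
#' @param dialect `"auto"` (default), `"tnt"`, or `"nexus"`.
#' @return a [morph_matrix()].
#' @export
parse_morph_matrix <- function(file = NULL, text = NULL,
                               dialect = c("auto", "tnt", "nexus")) {
  dialect <- match.arg(dialect)
  if (is.null(text)) text <- readLines(file, warn = FALSE, encoding = "UTF-8")
  text <- paste(text, collapse = "\n")
  if (dialect == "auto") {
    dialect <- if (grepl("#NEXUS", text, ignore.case = TRUE)) "nexus" else "tnt"
  }
  if (dialect == "tnt") parse_tnt(text) else parse_nexus(text)
}

read_rows <- function(toks, ntax, nchar_decl) {
  seqs <- list()
  order_seen <- character()
  i <- 1L
  while (i <= length(toks)) {
    name <- toks[i]
    if (name == ";") break
    if (i + 1L > length(toks) || toks[i + 1L] == ";")
      stop("taxon ", name, " has no character data")
    chunk <- ""
    j <- i + 1L
    # A row may be split into several whitespace-separated chunks.  While
    # the current taxon's row is still short of nchar the next token must
    # be sequence data (so bad symbols are reported as such, not mistaken
    # for taxon names); once complete, only data-shaped tokens that are
    # not known taxon names continue the row (interleaved format).
    while (j <= length(toks) && toks[j] != ";") {
      tok <- toks[j]
      cur <- if (is.null(seqs[[name]])) "" else seqs[[name]]
      incomplete <- nchar(cur) + nchar(chunk) < nchar_decl
      is_data <- grepl("^[-0-9a?−]+$", tok) && !(tok %in% names(seqs))
      # an incomplete row keeps digit-bearing tokens even when they hold
      # stray letters, so bad symbols are reported as symbols rather than
      # mistaken for the next taxon's name
      if (!is_data && !(incomplete && grepl("[0-9?]", tok))) break
      chunk <- paste0(chunk, tok)
      j <- j + 1L
    }
    if (!name %in% order_seen) order_seen <- c(order_seen, name)
    seqs[[name]] <- paste0(if (is.null(seqs[[name]])) "" else seqs[[name]],
                           chunk)
    i <- j
  }
  if (length(order_seen) != ntax)
    stop("declared ", ntax, " taxa but found ", length(order_seen))
  lens <- vapply(seqs, nchar, integer(1L))
  bad <- names(lens)[lens != nchar_decl]
  if (length(bad))
    stop("taxon ", bad[1L], " has ", lens[bad[1L]],
         " characters; expected ", nchar_decl)
  cells <- t(vapply(order_seen,
                    function(nm) decode_row(seqs[[nm]], nm),
                    integer(nchar_decl)))
  if (nchar_decl == 1L) cells <- matrix(cells, ncol = 1L,
                                        dimnames = list(order_seen, NULL))
  morph_matrix(cells, order_seen)
}

parse_tnt <- function(text) {
  text <- gsub("'[^']*'", " ", text)            # TNT title comment
  toks <- nexus_tokens(text)
  ix <- which(tolower(toks) == "xread")
  if (!length(ix)) stop("no xread block found")
  toks <- toks[-seq_len(ix[1L])]
  nc <- suppressWarnings(as.integer(toks[1L]))
  nt <- suppressWarnings(as.integer(toks[2L]))
  if (is.na(nc) || is.na(nt))
    stop("xread header must give nchar and ntax")
  read_rows(toks[-(1:2)], nt, nc)
}

parse_nexus <- function(text) {
  toks <- nexus_tokens(text)
  lt <- tolower(toks)
  mx <- which(lt == "matrix")
  if (!length(mx)) stop("no MATRIX command found in NEXUS input")
  # tolerate "NTAX = 5" split across tokens by re-scanning the raw text
  raw <- paste(toks, collapse = " ")
  num <- function(key) {
    m <- regmatches(raw, regexpr(paste0("(?i)", key, "\\s*=\\s*[0-9]+"), raw,
                                 perl = TRUE))
    if (!length(m)) stop("NEXUS DIMENSIONS must declare ", toupper(key))
    as.integer(sub(".*=\\s*", "", m))
  }
  nt <- num("ntax"); nc <- num("nchar")
  read_rows(toks[-seq_len(mx[1L])], nt, nc)
}

#' Write a character matrix in TNT or NEXUS form
#'
#' The inverse of [parse_morph_matrix()]: `parse(write(x))` reproduces `x`
#' exactly, including the distinction between missing and inapplicable
#' cells.
#'
#' @param x a [morph_matrix()].
#' @param file optional path; if `NULL` the text is returned invisibly.
#' @param dialect `"tnt"` or `"nexus"`.
#' @return the file content, invisibly, as a character vector of lines.
#' @export
write_morph_matrix <- function(x, file = NULL, dialect = c("tnt", "nexus")) {
  dialect <- match.arg(dialect)
  rows <- vapply(seq_len(n_taxa(x)), function(i) {
    paste(vapply(x$cells[i, ], cell_to_symbol, character(1L)), collapse = "")
  }, character(1L))
  name <- gsub("[^A-Za-z0-9_.]", "_", x$taxa)
  body <- paste(format(name, width = max(nchar(name)) + 2L), rows)
  out <- if (dialect == "tnt") {
    c("xread", paste(n_char(x), n_taxa(x)), body, ";")
  } else {
    c("#NEXUS", "BEGIN DATA;",
      paste0("  DIMENSIONS NTAX=", n_taxa(x), " NCHAR=", n_char(x), ";"),
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123456789a\" MISSING=? GAP=-;",
      "  MATRIX", paste0("    ", body), "  ;", "END;")
  }
  if (!is.null(file)) writeLines(out, file, useBytes = TRUE)
  invisible(out)
}

#' Read a first-appearance age table
#'
#' One row per taxon with the oldest and youngest possible age (Ma before
#' present, so larger numbers are older) of its first appearance.  Columns
#' are matched by name (`taxon`, `fad_oldest`, `fad_youngest`), or taken
#' positionally when names differ.
#'
#' @param file CSV/TSV path with a header row, or `NULL` if `df` is given.
#' @param df a data frame already in memory.
#' @return a data frame of class `age_table`.
#' @export
read_age_table <- function(file = NULL, df = NULL) {
  if (is.null(df)) {
    sep <- if (grepl("\\.tsv$", file)) "\t" else ","
    df <- utils::read.table(file, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, strip.white = TRUE)
  }
  want <- c("taxon", "fad_oldest", "fad_youngest")
  if (!all(want %in% names(df))) {
    if (ncol(df) < 3L) stop("age table needs taxon + two age columns")
    names(df)[1:3] <- want
  }
  df <- df[, want]
  df$fad_oldest <- as.numeric(df$fad_oldest)
  df$fad_youngest <- as.numeric(df$fad_youngest)
  if (anyDuplicated(df$taxon))
    stop("duplicate taxa in age table: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  if (any(is.na(df$fad_oldest)) || any(is.na(df$fad_youngest)))
    stop("non-numeric ages in age table")
  if (any(df$fad_oldest < 0) || any(df$fad_youngest < 0))
    stop("ages must be non-negative (Ma before present)")
  bad <- df$taxon[df$fad_youngest > df$fad_oldest]
  if (length(bad))
    stop("fad_youngest exceeds fad_oldest for: ", paste(bad, collapse = ", "))
  class(df) <- c("age_table", "data.frame")
  df
}

#' Check that a table covers a set of taxa
#'
#' @param tab an `age_table` or `area_table`.
#' @param taxa character vector of required taxon labels (e.g. the rows of
#'   a matrix or the tips of a tree).
#' @return `tab`, invisibly; errors listing any absent taxa.
#' @export
validate_taxa <- function(tab, taxa) {
  absent <- setdiff(taxa, tab$taxon)
  if (length(absent))
    stop("table lacks taxa: ", paste(absent, collapse = ", "))
  invisible(tab)
}

#' Read a taxon-to-area table
#'
#' One row per taxon with exactly one geographic area drawn from a fixed
#' area universe (by default the six continents of [CONTINENTS]).
#'
#' @inheritParams read_age_table
#' @param levels the area universe; states are coded `0 .. length(levels)-1`
#'   in this order.
#' @return a data frame of class `area_table` with columns `taxon`, `area`.
#' @export
read_area_table <- function(file = NULL, df = NULL, levels = CONTINENTS) {
  if (is.null(df)) {
    sep <- if (grepl("\\.tsv$", file)) "\t" else ","
    df <- utils::read.table(file, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, strip.white = TRUE)
  }
  if (!all(c("taxon", "area") %in% names(df))) names(df)[1:2] <- c("taxon", "area")
  df <- df[, c("taxon", "area")]
  if (anyDuplicated(df$taxon))
    stop("duplicate taxa in area table: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  bad <- setdiff(df$area, levels)
  if (length(bad))
    stop("unknown area(s): ", paste(bad, collapse = ", "))
  attr(df, "area_levels") <- levels
  class(df) <- c("area_table", "data.frame")
  df
}

#' Build the single geographic character
#'
#' Converts an area table into a one-state-per-taxon discrete character
#' over the area universe, the form used by the ancestral-area analyses.
#' The mapping is by area identity, so it does not depend on the order of
#' `taxa`.
#'
#' @param areas an [read_area_table()] result.
#' @param taxa ordered taxon labels the character should cover.
#' @return integer vector of 0-based state codes named by taxon, with the
#'   area universe in `attr(, "levels")`.
#' @export
build_area_character <- function(areas, taxa) {
  validate_taxa(areas, taxa)
  levels <- attr(areas, "area_levels")
  code <- match(areas$area, levels) - 1L
  names(code) <- areas$taxon
  out <- code[taxa]
  names(out) <- taxa
  attr(out, "levels") <- levels
  out
}

#' @export
print.age_table <- function(x, ...) {
  cat("First-appearance ages for", nrow(x), "taxa (Ma)\n")
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
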