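#' Read a character matrix from CSV/TSV or NEXUS
#'
#' CSV/TSV: first column = carrier ids, header row = feature ids, cells
#' numeric or \code{"?"} (missing). NEXUS: a CHARACTERS or DATA block with
#' \code{DATATYPE=STANDARD}; the MISSING symbol (default \code{?}) marks
#' missing entries and the GAP symbol (default \code{-}) is treated as
#' missing too (with a message). Interleaved matrices are accepted.
#'
#' State symbols from the FORMAT line's SYMBOLS list are mapped to integer
#' codes. When every symbol is a digit, the digit's own value is used (so
#' \code{SYMBOLS="123"} yields the codes 1, 2, 3 as printed in a table
#' using those labels, and the default \code{"01"} yields 0/1); otherwise
#' symbols are coded positionally, first symbol -> 0. Morphological NEXUS
#' dialects vary on this point, hence the documented rule.
#'
#' @param path file path.
#' @param format \code{"csv"}, \code{"tsv"} or \code{"nexus"}; default
#'   guessed from the file extension.
#' @param field coefficient field for the result; defaults as in
#'   \code{\link{character_matrix}}.
#' @return a \code{\link{character_matrix}}.
#' @export
read_character_matrix <- function(path, format = NULL, field = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", nex = "nexus",
                     nexus = "nexus",
                     stop("cannot guess format from extension; pass format="))
  }
  format <- match.arg(format, c("csv", "tsv", "nexus"))
  if (format == "nexus") return(read_nexus_matrix(path, field = field))

  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus at least one feature")
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  vals[vals %in% c("?", "")] <- NA
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell at line ", bad[1L, 1L] + 1L, ", column ",
         bad[1L, 2L] + 1L, ": \"", vals[bad[1L, , drop = FALSE]], "\"")
  }
  character_matrix(num, field = field, carrier_ids = ids,
                   feature_ids = colnames(df)[-1L])
}

read_nexus_matrix <- function(path, field = NULL) {
  txt <- readLines(path, warn = FALSE)
  txt <- gsub("\\[[^]]*\\]", "", txt)            # strip single-line comments
  joined <- paste(txt, collapse = "\n")
  if (!grepl("#NEXUS", joined, ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header)")

  fmt <- regmatches(joined, regexpr("(?is)FORMAT[^;]*;", joined, perl = TRUE))
  symbols <- "01"; missing_sym <- "?"; gap_sym <- "-"
  if (length(fmt)) {
    grab <- function(key, default) {
      m <- regmatches(fmt, regexpr(paste0("(?i)", key,
                                          "\\s*=\\s*(\"[^\"]*\"|[^;\\s]+)"),
                                   fmt, perl = TRUE))
      if (!length(m)) return(default)
      v <- sub(paste0("(?i)", key, "\\s*=\\s*"), "", m, perl = TRUE)
      gsub("[\" ]", "", v)
    }
    symbols <- grab("SYMBOLS", symbols)
    missing_sym <- grab("MISSING", missing_sym)
    gap_sym <- grab("GAP", gap_sym)
    if (grepl("(?i)DATATYPE\\s*=", fmt, perl = TRUE) &&
        !grepl("(?i)DATATYPE\\s*=\\s*STANDARD", fmt, perl = TRUE))
      stop("only DATATYPE=STANDARD character blocks are supported")
  }
  syms <- strsplit(symbols, "")[[1L]]
  codes <- if (all(grepl("^[0-9]$", syms))) as.numeric(syms)
           else seq_along(syms) - 1

  mat_m <- regmatches(joined, regexpr("(?is)MATRIX(.*?);", joined, perl = TRUE))
  if (!length(mat_m)) stop("no MATRIX command found")
  body <- sub("(?is)^MATRIX", "", mat_m, perl = TRUE)
  body <- sub(";$", "", body)
  lines <- trimws(strsplit(body, "\n")[[1L]])
  lines <- lines[nzchar(lines)]

  rows <- list()   # taxon -> concatenated state string (handles interleaving)
  order_seen <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^('[^']+'|\"[^\"]+\"|\\S+)\\s+(.*)$", ln))[[1L]]
    if (length(m) < 3L) stop("cannot parse matrix row: ", ln)
    taxon <- gsub("^['\"]|['\"]$", "", m[2L])
    states <- gsub("\\s", "", m[3L])
    if (!taxon %in% order_seen) { order_seen <- c(order_seen, taxon); rows[[taxon]] <- "" }
    rows[[taxon]] <- paste0(rows[[taxon]], states)
  }
  chars <- lapply(order_seen, function(tx) strsplit(rows[[tx]], "")[[1L]])
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L)
    stop("ragged NEXUS matrix: taxa have differing character counts (",
         paste(unique(lens), collapse = ", "), ")")
  m <- lens[1L]
  V <- matrix(NA_real_, length(order_seen), m)
  n_gap <- 0L
  for (i in seq_along(order_seen)) for (j in seq_len(m)) {
    ch <- chars[[i]][j]
    if (ch == missing_sym) next
    if (ch == gap_sym) { n_gap <- n_gap + 1L; next }
    k <- match(ch, syms)
    if (is.na(k)) stop("unknown symbol \"", ch, "\" at taxon ", order_seen[i],
                       ", character ", j)
    V[i, j] <- codes[k]
  }
  if (n_gap > 0L) message("treating ", n_gap, " gap symbol(s) as missing")
  character_matrix(V, field = field, carrier_ids = order_seen,
                   feature_ids = paste0("char_", seq_len(m)))
}

#' Write a character matrix to CSV/TSV or NEXUS
#'
#' Inverse of \code{\link{read_character_matrix}}; missing entries are
#' written as \code{?}. The NEXUS writer emits a non-interleaved
#' DATATYPE=STANDARD CHARACTERS block (integer states only).
#'
#' @param M a \code{\link{character_matrix}}.
#' @param path output path.
#' @param format \code{"csv"}, \code{"tsv"} or \code{"nexus"}.
#' @export
write_character_matrix <- function(M, path, format = c("csv", "tsv", "nexus")) {
  M <- as_character_matrix(M)
  format <- match.arg(format)
  if (format == "nexus") {
    obs <- M$values[!M$missing]
    if (any(obs != round(obs)) || any(obs < 0) || any(obs > 9))
      stop("NEXUS STANDARD output needs integer states in 0..9")
    syms <- sort(unique(obs))
    cells <- matrix(as.character(M$values), nrow(M$values))
    cells[M$missing] <- "?"
    pad <- max(nchar(M$carrier_ids))
    lines <- c("#NEXUS", "BEGIN CHARACTERS;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                       nrow(M$values), ncol(M$values)),
               sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
                       paste(syms, collapse = "")),
               "  MATRIX",
               vapply(seq_len(nrow(M$values)), function(i)
                 sprintf("    %-*s %s", pad, M$carrier_ids[i],
                         paste(cells[i, ], collapse = "")), ""),
               "  ;", "END;")
    writeLines(lines, path)
    return(invisible(path))
  }
  cells <- matrix(as.character(M$values), nrow(M$values))
  cells[M$missing] <- "?"
  df <- data.frame(carrier = M$carrier_ids, cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("carrier", M$feature_ids)
  utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize analysis objects as JSON
#'
#' Writers for decompositions and frequency models, with explicit field,
#' convention, tolerance and seed metadata so reports are reproducible and
#' self-describing. Keys are emitted in a fixed order.
#'
#' @param x object to serialize.
#' @param path output path, or \code{NULL} to return the JSON string.
#' @param meta named list of extra metadata (tolerance, seed, ...).
#' @export
write_decomposition_json <- function(x, path = NULL, meta = list()) {
  stopifnot(inherits(x, "rank_decomposition"))
  obj <- c(list(object = "rank_decomposition", field = x$field,
                rank = x$rank,
                reconstruction_error = x$reconstruction_error,
                carrier_ids = x$carrier_ids, feature_ids = x$feature_ids,
                terms = lapply(x$terms, function(tm)
                  list(a = unname(tm$a), b = unname(tm$b)))),
           meta)
  emit_json(obj, path)
}

#' @rdname write_decomposition_json
#' @export
write_frequency_json <- function(x, path = NULL, meta = list()) {
  stopifnot(inherits(x, "frequency_model"))
  obj <- c(list(object = "frequency_model", convention = x$convention,
                feature_ids = x$feature_ids,
                marginals = unname(x$marginals),
                pairwise = x$pairwise,
                cooccurrence = x$cooccurrence, Z = x$Z),
           meta)
  emit_json(obj, path)
}

emit_json <- function(obj, path) {
  obj <- Filter(Negate(is.null), obj)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Feature-space JSON (schema "morphospace-v1")
#'
#' Lossless round-trip serialization of a \code{\link{feature_space}} (with
#' its admissible sections) and of section lists. The schema is versioned;
#' readers reject unknown versions.
#'
#' @param space a \code{feature_space}.
#' @param sections optional list of \code{section}s stored alongside.
#' @param path output path, or \code{NULL} for the JSON string.
#' @export
write_space_json <- function(space, path = NULL, sections = NULL) {
  stopifnot(inherits(space, "feature_space"))
  obj <- list(schema = "morphospace-v1",
              base = space$base,
              fibers = space$fibers,
              admissible = if (is.null(space$constraints)) NULL else
                lapply(space$constraints, as.list))
  if (!is.null(sections))
    obj$sections <- lapply(sections, function(s)
      list(label = s$label, assignment = as.list(s$assignment)))
  emit_json(obj, path)
}

#' @rdname write_space_json
#' @param x JSON string or file path to read back.
#' @return \code{read_space_json}: list with \code{space} and
#'   \code{sections} (possibly empty).
#' @export
read_space_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (!identical(obj$schema, "morphospace-v1"))
    stop("unsupported schema: ", obj$schema)
  fibers <- lapply(obj$fibers, function(f) as.character(unlist(f)))
  constraints <- if (is.null(obj$admissible)) NULL else
    lapply(obj$admissible, function(a)
      stats::setNames(as.character(unlist(a)), names(a)))
  space <- feature_space(as.character(unlist(obj$base)), fibers, constraints)
  sections <- if (is.null(obj$sections)) list() else
    lapply(obj$sections, function(s)
      section(stats::setNames(as.character(unlist(s$assignment)),
                              names(s$assignment)),
              label = s$label, space = space))
  list(space = space, sections = sections)
}
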