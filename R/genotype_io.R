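#' Construct a multilocus genotype table
#'
#' A `genotype_table` holds diploid, co-dominant genotypes (microsatellite
#' allele codes) for a set of individuals, together with sex and the breeding
#' seasons in which each individual was recorded.  Allele codes are arbitrary
#' integer labels (typically fragment lengths); they are compared by equality
#' only, never by magnitude.  Within a genotype the two allele codes are
#' stored in sorted order so that genotypes are unordered pairs.
#'
#' @param ids character vector of unique individual identifiers.
#' @param sex character vector, one of `"female"`, `"male"`, `"unknown"`.
#' @param years list of integer vectors: the breeding seasons (calendar year
#'   of season start) in which each individual was recorded.
#' @param loci character vector of locus names (fixed order).
#' @param a1,a2 integer matrices (`length(ids)` x `length(loci)`) of allele
#'   codes; `NA` in either matrix marks the genotype as missing.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, sex, years, loci, a1, a2) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sex <- match.arg(as.character(sex), c("female", "male", "unknown"),
                   several.ok = TRUE)
  if (length(sex) == 1L) sex <- rep(sex, length(ids))
  stopifnot(length(sex) == length(ids), length(years) == length(ids))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(length(ids), length(loci))) ||
      !all(dim(a2) == dim(a1)))
    stop("allele matrices must be length(ids) x length(loci)")
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  swap <- !miss & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  if (any(!miss & (a1 <= 0L | a2 <= 0L)))
    stop("allele codes must be positive integers (use NA for missing)")
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, sex = sex, years = years,
                 loci = as.character(loci), a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals,",
      length(x$loci), "loci,",
      sum(is.na(x$a1)), "missing genotypes\n")
  invisible(x)
}

n_individuals <- function(table) length(table$ids)

parse_years_field <- function(s) {
  lapply(strsplit(as.character(s), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(trimws(v))]
    sort(unique(as.integer(v)))
  })
}

parse_allele_cell <- function(v, path, col) {
  v <- trimws(as.character(v))
  v[v == "" | toupper(v) == "NA"] <- NA
  out <- suppressWarnings(as.integer(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad))
    stop(sprintf("parse error in %s, column %s, data row %d: '%s'",
                 path, col, bad[1], v[bad[1]]))
  out[!is.na(out) & out == 0L] <- NA_integer_
  out
}

#' Read a genotype table
#'
#' Two dialects are supported.  `"csv"` expects a header row with columns
#' `id`, `sex`, `years` (semicolon-separated seasons), then two columns per
#' locus named `<locus>_1` and `<locus>_2`.  Missing genotypes may be coded as
#' empty cells, `NA`, or `0`.  `"genepop"` reads a standard GenePop file
#' (2- or 3-digit concatenated allele encoding, `00`/`000` missing); sex and
#' seasons are then taken from an optional sidecar CSV with columns `id`,
#' `sex`, `years`.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"genepop"`.
#' @param sidecar optional path to a metadata CSV for the GenePop dialect.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, dialect = c("csv", "genepop"),
                           sidecar = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") read_genotypes_csv(path) else
    read_genotypes_genepop(path, sidecar)
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", strip.white = TRUE)
  need <- c("id", "sex", "years")
  if (!all(need %in% names(df)[1:3]))
    stop("schema error in ", path,
         ": first columns must be id, sex, years")
  acols <- setdiff(names(df), need)
  if (length(acols) %% 2L != 0L)
    stop("schema error in ", path, ": odd number of allele columns (",
         length(acols), "); expected <locus>_1, <locus>_2 per locus")
  l1 <- acols[seq(1L, length(acols), by = 2L)]
  l2 <- acols[seq(2L, length(acols), by = 2L)]
  loci <- sub("_1$", "", l1)
  if (!identical(paste0(loci, "_1"), l1) || !identical(paste0(loci, "_2"), l2))
    stop("schema error in ", path,
         ": allele columns must come in <locus>_1, <locus>_2 pairs")
  n <- nrow(df)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) {
    a1[, j] <- parse_allele_cell(df[[l1[j]]], path, l1[j])
    a2[, j] <- parse_allele_cell(df[[l2[j]]], path, l2[j])
  }
  sex <- tolower(trimws(df$sex))
  sex[sex %in% c("f", "female")] <- "female"
  sex[sex %in% c("m", "male")] <- "male"
  sex[!(sex %in% c("female", "male"))] <- "unknown"
  genotype_table(df$id, sex, parse_years_field(df$years), loci, a1, a2)
}

read_genotypes_genepop <- function(path, sidecar = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("parse error: GenePop file too short: ", path)
  body <- lines[-1L]  # first line is a title
  popat <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(popat)) stop("parse error: no 'Pop' line in ", path)
  locus_lines <- body[seq_len(popat[1] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",", fixed = TRUE)))
  loci <- loci[nzchar(loci)]
  ind_lines <- body[-seq_len(popat[1])]
  ind_lines <- ind_lines[!grepl("^\\s*pop\\s*$", ind_lines,
                                ignore.case = TRUE)]
  ids <- character(length(ind_lines))
  a1 <- matrix(NA_integer_, length(ind_lines), length(loci))
  a2 <- matrix(NA_integer_, length(ind_lines), length(loci))
  for (i in seq_along(ind_lines)) {
    parts <- strsplit(ind_lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop(sprintf("parse error in %s, individual line %d: missing comma",
                   path, i))
    ids[i] <- trimws(parts[1])
    gstr <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(gstr) != length(loci))
      stop(sprintf(
        "parse error in %s, individual line %d: %d genotype fields for %d loci",
        path, i, length(gstr), length(loci)))
    w <- nchar(gstr) / 2L
    if (any(w != floor(w)) || any(!w %in% c(2L, 3L)))
      stop(sprintf("parse error in %s, individual line %d: allele field '%s'",
                   path, i, gstr[which(!w %in% c(2L, 3L))[1]]))
    x1 <- as.integer(substr(gstr, 1L, w))
    x2 <- as.integer(substr(gstr, w + 1L, 2L * w))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  sex <- rep("unknown", length(ids))
  years <- rep(list(integer(0)), length(ids))
  if (!is.null(sidecar)) {
    meta <- utils::read.csv(sidecar, colClasses = "character",
                            strip.white = TRUE)
    m <- match(ids, meta$id)
    sex[!is.na(m)] <- tolower(meta$sex[m[!is.na(m)]])
    years[!is.na(m)] <- parse_years_field(meta$years[m[!is.na(m)]])
  }
  genotype_table(ids, sex, years, loci, a1, a2)
}

#' Write a genotype table as CSV
#'
#' Inverse of the CSV dialect of [read_genotypes()]: a round trip reproduces
#' the table exactly (allele codes, missing pattern, locus order).
#'
#' @param table a [genotype_table()].
#' @param path output file path.
#' @export
write_genotypes <- function(table, path) {
  df <- data.frame(
    id = table$ids, sex = table$sex,
    years = vapply(table$years, paste, "", collapse = ";"),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(table$loci)) {
    df[[paste0(table$loci[j], "_1")]] <- table$a1[, j]
    df[[paste0(table$loci[j], "_2")]] <- table$a2[, j]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Estimate per-locus allele frequencies
#'
#' Frequencies are allele-copy proportions among non-missing genotypes: the
#' frequency of allele `a` at locus `l` is its count among the `2 * n_typed`
#' gene copies at `l`.  All genotyped individuals are pooled (optionally a
#' subset via `ids`).
#'
#' @param table a [genotype_table()].
#' @param ids optional character vector restricting the estimate to a subset
#'   of individuals.
#' @return An object of class `allele_freqs`: list with `loci`, `freqs`
#'   (per-locus named numeric vectors summing to 1) and `n_typed` (non-missing
#'   genotypes per locus).
#' @export
allele_frequencies <- function(table, ids = NULL) {
  rows <- if (is.null(ids)) seq_along(table$ids) else
    match(ids, table$ids)
  if (anyNA(rows)) stop("unknown id(s) in 'ids'")
  freqs <- vector("list", length(table$loci))
  n_typed <- integer(length(table$loci))
  for (j in seq_along(table$loci)) {
    al <- c(table$a1[rows, j], table$a2[rows, j])
    al <- al[!is.na(al)]
    if (!length(al))
      stop("locus '", table$loci[j], "' has zero non-missing genotypes")
    n_typed[j] <- length(al) %/% 2L
    tab <- table(al)
    freqs[[j]] <- stats::setNames(as.numeric(tab) / length(al),
                                  names(tab))
  }
  names(freqs) <- table$loci
  structure(list(loci = table$loci, freqs = freqs,
                 n_typed = stats::setNames(n_typed, table$loci)),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("allele_freqs:", length(x$loci), "loci;",
      "alleles per locus:",
      paste(vapply(x$freqs, length, 0L), collapse = ", "), "\n")
  invisible(x)
}

compute_pair_flags <- function(df) {
  ord <- order(df$year, df$female_id, df$male_id)
  df <- df[ord, , drop = FALSE]
  key <- paste(df$female_id, df$male_id, sep = "\r")
  df$first_observation <- !duplicated(key)
  df$remated <- duplicated(key)
  rownames(df) <- NULL
  df
}

validate_pairs <- function(df, table) {
  for (col in c("female_id", "male_id")) {
    m <- match(df[[col]], table$ids)
    if (anyNA(m))
      stop("pair table refers to unknown id(s): ",
           paste(unique(df[[col]][is.na(m)]), collapse = ", "))
    want <- if (col == "female_id") "female" else "male"
    bad <- table$sex[m] != want
    if (any(bad))
      stop("sex mismatch: ", paste(unique(df[[col]][bad]), collapse = ", "),
           " recorded as ", col, " but not of sex ", want)
  }
  ids_by_year <- split(c(df$female_id, df$male_id), c(df$year, df$year))
  for (y in names(ids_by_year)) {
    dup <- ids_by_year[[y]][duplicated(ids_by_year[[y]])]
    if (length(dup))
      stop("individual(s) in two pairs in year ", y, ": ",
           paste(unique(dup), collapse = ", "))
  }
  invisible(df)
}

#' Build breeding-pair records from a data frame
#'
#' Computes, by scanning seasons in ascending order, the `first_observation`
#' flag (first season a female-male combination appears) and the `remated`
#' flag (the combination also bred together in a previous recorded season).
#' Flags do not depend on input row order.
#'
#' @param df data frame with columns `year`, `female_id`, `male_id`.
#' @param table a [genotype_table()] used to validate ids and sexes.
#' @return A data frame of class `pair_records` with columns `year`,
#'   `female_id`, `male_id`, `remated`, `first_observation`.
#' @export
pair_records <- function(df, table) {
  df <- data.frame(year = as.integer(df$year),
                   female_id = as.character(df$female_id),
                   male_id = as.character(df$male_id),
                   stringsAsFactors = FALSE)
  validate_pairs(df, table)
  df <- compute_pair_flags(df)
  class(df) <- c("pair_records", "data.frame")
  df
}

#' Read a breeding-pair table
#'
#' @param path CSV file with columns `year`, `female_id`, `male_id`.
#' @param table a [genotype_table()] used for validation.
#' @return A `pair_records` data frame; see [pair_records()].
#' @export
read_pairs <- function(path, table) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("year", "female_id", "male_id")
  if (!all(need %in% names(df)))
    stop("schema error in ", path, ": need columns year, female_id, male_id")
  pair_records(df[need], table)
}

#' Write a breeding-pair table as CSV
#' @param pairs a `pair_records` data frame.
#' @param path output file path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(pairs[c("year", "female_id", "male_id")], path,
                   row.names = FALSE)
  invisible(path)
}
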