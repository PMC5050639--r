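#' Validate a marker score matrix
#'
#' A marker matrix is a plain numeric matrix of lines (rows) by markers
#' (columns).  Raw genotypes of inbred lines are scored `-1` / `+1` with `NA`
#' for missing calls; imputed matrices may hold any real value in
#' `[-1, +1]`.  Row and column names are the line and marker identifiers and
#' must be present and unique.
#'
#' @param m numeric matrix with unique `rownames` (lines) and `colnames`
#'   (markers).
#' @param raw if `TRUE`, additionally require every non-missing entry to be
#'   exactly `-1` or `+1` (pre-imputation scores).
#' @return `m`, invisibly, after validation.
#' @export
as_marker_matrix <- function(m, raw = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    fail("marker matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    fail("marker matrix needs line ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(m))) fail("duplicate line identifiers")
  if (anyDuplicated(colnames(m))) fail("duplicate marker identifiers")
  v <- m[!is.na(m)]
  if (raw) {
    if (!all(v %in% c(-1, 1)))
      fail("raw marker scores must be -1, +1 or NA")
  } else if (length(v) && (min(v) < -1 || max(v) > 1)) {
    fail("marker scores must lie in [-1, +1]")
  }
  invisible(m)
}

#' Read a marker score matrix
#'
#' Reads genotypes of inbred lines into the `{-1, +1, NA}` score coding.
#' Three dialects are supported:
#' \describe{
#'   \item{`delimited`}{tab-separated table, header row of marker ids, first
#'     column of line ids, missing written as `NA` (the package's native
#'     format, see [write_marker_matrix()]).}
#'   \item{`vcf`}{standard VCF via the \pkg{vcfR} package.  The reference
#'     allele maps to `+1`, the alternate allele to `-1`.  Heterozygous calls
#'     have no representation in the inbred `{-1, 1}` coding and are set to
#'     missing with a warning reporting their count.  Sites with more than
#'     one alternate allele are an error.}
#'   \item{`hapmap`}{HapMap-style text (11 annotation columns `rs#`,
#'     `alleles`, `chrom`, `pos`, ... then one column per line, single-letter
#'     genotypes).  The first allele listed in the `alleles` column maps to
#'     `+1`, the second to `-1`; `N` and ambiguity codes become missing.}
#' }
#'
#' @param path file path.
#' @param dialect one of `"delimited"`, `"vcf"`, `"hapmap"`.
#' @return numeric matrix, lines x markers (see [as_marker_matrix()]).
#' @export
read_marker_matrix <- function(path, dialect = c("delimited", "vcf", "hapmap")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) fail("file not found: %s", path)
  m <- switch(dialect,
    delimited = read_delim_scores(path),
    vcf       = read_vcf_scores(path),
    hapmap    = read_hapmap_scores(path))
  as_marker_matrix(m)
  m
}

read_delim_scores <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         row.names = 1, na.strings = "NA",
                         colClasses = "character")
  m <- as.matrix(d)
  storage.mode(m) <- "numeric"
  m
}

read_vcf_scores <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    fail("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) fix <- matrix(fix, nrow = 1,
                                     dimnames = list(NULL, names(fix)))
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    fail("more than two alleles at a marker (multi-allelic ALT)")
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  if (anyDuplicated(ids)) fail("duplicate marker identifiers in VCF")
  code <- gsub("|", "/", gt, fixed = TRUE)
  score <- matrix(NA_real_, nrow(code), ncol(code), dimnames = dimnames(code))
  score[code %in% c("0/0", "0")] <- 1
  score[code %in% c("1/1", "1")] <- -1
  het <- code %in% c("0/1", "1/0")
  if (any(het))
    warning(sprintf("%d heterozygous calls set to missing (inbred coding)",
                    sum(het)), call. = FALSE)
  m <- t(score)                       # lines x markers
  colnames(m) <- ids
  m
}

read_hapmap_scores <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         comment.char = "", colClasses = "character")
  if (ncol(d) < 12) fail("HapMap file needs 11 annotation columns plus lines")
  alleles <- strsplit(d[[2]], "/", fixed = TRUE)
  if (any(lengths(alleles) != 2))
    fail("more than two alleles at a marker")
  a1 <- vapply(alleles, `[`, character(1), 1)
  a2 <- vapply(alleles, `[`, character(1), 2)
  geno <- as.matrix(d[, -(1:11), drop = FALSE])
  score <- matrix(NA_real_, nrow(geno), ncol(geno))
  score[geno == a1] <- 1
  score[geno == a2] <- -1
  het <- !is.na(geno) & geno != "N" & geno != a1 & geno != a2
  if (any(het))
    warning(sprintf("%d heterozygous/ambiguous calls set to missing", sum(het)),
            call. = FALSE)
  m <- t(score)
  colnames(m) <- d[[1]]
  rownames(m) <- colnames(d)[-(1:11)]
  if (anyDuplicated(colnames(m))) fail("duplicate marker identifiers")
  m
}

#' Write a marker score matrix
#'
#' Writes the native delimited format: tab-separated, header row of marker
#' ids (first field `line`), one row per line, missing entries as `NA`.
#' Integer-valued scores are written without a decimal point so that a
#' write/read/write cycle is byte-identical.
#'
#' @param m marker matrix (see [as_marker_matrix()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(m, path) {
  as_marker_matrix(m)
  ch <- matrix(fmt_score(m), nrow(m), dimnames = dimnames(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("line", colnames(m)), collapse = "\t"), con)
  body <- apply(ch, 1, paste, collapse = "\t")
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

fmt_score <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "NA"
  i <- !is.na(x)
  whole <- i & x == round(x)
  out[whole] <- sprintf("%d", as.integer(x[whole]))
  out[i & !whole] <- format(x[i & !whole], digits = 17, trim = TRUE,
                            scientific = FALSE)
  out
}

#' Read / write a genetic map
#'
#' Native map format: TSV with columns `marker`, `chrom`, `pos_cM` and
#' optionally `bin` (integer recombination-bin label, may be empty).
#'
#' @param path file path.
#' @return `read_genetic_map`: data frame with columns `marker`, `chrom`,
#'   `pos_cM`, `bin`.
#' @export
read_genetic_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         colClasses = c(marker = "character",
                                        chrom = "character"))
  if (!all(c("marker", "chrom", "pos_cM") %in% names(d)))
    fail("map needs columns marker, chrom, pos_cM")
  if (is.null(d$bin)) d$bin <- NA_integer_
  as_genetic_map(d)
}

#' @rdname read_genetic_map
#' @param map genetic map data frame.
#' @export
write_genetic_map <- function(map, path) {
  as_genetic_map(map)
  utils::write.table(map[, c("marker", "chrom", "pos_cM", "bin")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a genetic map
#'
#' @param map data frame with columns `marker`, `chrom`, `pos_cM` and
#'   optional integer `bin`.
#' @param markers optional marker ids that must each have exactly one map
#'   record (e.g. `colnames` of an accompanying marker matrix).
#' @return `map` with `bin` column present, invisibly validated.
#' @export
as_genetic_map <- function(map, markers = NULL) {
  if (!all(c("marker", "chrom", "pos_cM") %in% names(map)))
    fail("map needs columns marker, chrom, pos_cM")
  if (anyDuplicated(map$marker)) fail("duplicate markers in map")
  if (any(!is.finite(map$pos_cM)) || any(map$pos_cM < 0))
    fail("map positions must be finite and >= 0")
  if (is.null(map$bin)) map$bin <- NA_integer_
  if (!is.null(markers) && !all(markers %in% map$marker))
    fail("markers missing from map: %s",
         paste(utils::head(setdiff(markers, map$marker), 5), collapse = ", "))
  map
}

#' Per-marker minor allele frequency
#'
#' The `+1`-allele frequency of a marker is `p = (mean(x) + 1) / 2` over its
#' non-missing scores (for `{-1, +1}` scores this is exactly the fraction of
#' `+1` calls); the MAF is `min(p, 1 - p)`.
#'
#' @param m marker matrix.
#' @param marker optional single marker id; if omitted, a named vector over
#'   all markers is returned.
#' @return MAF in `[0, 0.5]` (`NaN` for all-missing markers when vectorised;
#'   an error for an explicit all-missing `marker`).
#' @export
marker_maf <- function(m, marker = NULL) {
  p <- (colMeans(m, na.rm = TRUE) + 1) / 2
  maf <- pmin(p, 1 - p)
  if (is.null(marker)) return(maf)
  if (!marker %in% colnames(m)) fail("unknown marker: %s", marker)
  out <- maf[[marker]]
  if (is.nan(out)) fail("marker %s has no observed entries", marker)
  out
}

#' Per-marker missing fraction
#' @param m marker matrix.
#' @return named vector of missing fractions in `[0, 1]`.
#' @export
missing_fraction <- function(m) colMeans(is.na(m))

#' Filter markers on missingness and minor allele frequency
#'
#' Keeps markers whose missing fraction is at most `max_missing` and whose
#' MAF is at least `min_maf` (all-missing markers are always dropped).  The
#' line set and the order of surviving markers are unchanged; the operation
#' is idempotent.
#'
#' @param m marker matrix.
#' @param max_missing maximum tolerated missing fraction in `[0, 1]`.
#' @param min_maf minimum minor allele frequency in `[0, 0.5]`.
#' @return filtered marker matrix (warning if no marker survives).
#' @export
filter_markers <- function(m, max_missing = 0.5, min_maf = 0.1) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 0.5)
  maf <- marker_maf(m)
  keep <- missing_fraction(m) <= max_missing & !is.nan(maf) & maf >= min_maf
  if (!any(keep)) warning("no markers pass the filters", call. = FALSE)
  m[, keep, drop = FALSE]
}

#' Realized additive relationship matrix
#'
#' Marker-derived kinship among lines, `A = W W' / c`, where `W` is the
#' column-mean-centred score matrix and `c = sum_k 4 p_k (1 - p_k)` is the
#' summed expected variance of a `{-1, +1}` score at the observed
#' `+1`-allele frequencies `p_k`.  Missing entries are mean-filled per marker
#' before centring (i.e. the relationship of an incomplete matrix is that of
#' its mean-imputed completion).  The normalisation `c` is a pure scale
#' factor: mixed-model association p-values are invariant to it.
#'
#' For numerical stability `eps * I` with `eps = 1e-6 * trace(A) / n` is
#' added before returning, which keeps the smallest eigenvalue above
#' `-1e-8` even for rank-deficient panels.
#'
#' @param m marker matrix (raw or imputed; missing entries allowed).
#' @return symmetric lines x lines matrix.
#' @export
realized_relationship <- function(m) {
  as_marker_matrix(m)
  n <- nrow(m)
  if (n < 2) fail("need at least 2 lines for a relationship matrix")
  mu <- colMeans(m, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu))) fail("all-missing marker column")
  W <- sweep(m, 2, mu)
  W[is.na(W)] <- 0                     # mean-filled entries are centred zeros
  p <- (mu + 1) / 2
  cc <- sum(4 * p * (1 - p))
  if (cc <= 0) fail("zero-variance marker matrix")
  A <- tcrossprod(W) / cc
  A <- (A + t(A)) / 2
  A + diag(1e-6 * sum(diag(A)) / n, n)
}
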