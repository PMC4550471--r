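#' Assemble a per-locus read-count table
#'
#' The package's central data structure is an ordinary tibble in "wide count"
#' form: one row per locus, a `locus_id` column, and for every sample `s` a
#' pair of integer columns `<s>_N` (total mapped reads) and `<s>_X`
#' (variant-allele reads). Optional `ref` / `alt` columns carry nucleotides
#' for allele-aware output. `locus_id` values of the form `"chrom:pos"` are
#' understood as 1-based genomic coordinates by the VCF writer.
#'
#' @param locus_id character vector of locus identifiers.
#' @param totals integer matrix (loci x samples) of total read counts N.
#' @param variants integer matrix of variant-read counts X, same shape.
#' @param samples sample names; defaults to `S1..Sn`.
#' @param ref,alt optional per-locus reference / variant alleles (A,C,G,T).
#' @return a tibble in wide count form.
#' @examples
#' count_table("chr1:100", matrix(c(10L, 8L), 1), matrix(c(2L, 0L), 1))
#' @export
count_table <- function(locus_id, totals, variants, samples = NULL,
                        ref = NULL, alt = NULL) {
  totals <- as.matrix(totals)
  variants <- as.matrix(variants)
  storage.mode(totals) <- "integer"
  storage.mode(variants) <- "integer"
  if (!identical(dim(totals), dim(variants))) {
    stop("`totals` and `variants` must have identical dimensions", call. = FALSE)
  }
  if (length(locus_id) != nrow(totals)) {
    stop("`locus_id` length must equal the number of loci (rows)", call. = FALSE)
  }
  validate_counts(totals, variants)
  n <- ncol(totals)
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  if (length(samples) != n) stop("`samples` length must equal ncol(totals)", call. = FALSE)
  cols <- vector("list", 2L * n)
  nms <- character(2L * n)
  for (i in seq_len(n)) {
    cols[[2L * i - 1L]] <- totals[, i]
    cols[[2L * i]] <- variants[, i]
    nms[2L * i - 1L] <- paste0(samples[i], "_N")
    nms[2L * i] <- paste0(samples[i], "_X")
  }
  names(cols) <- nms
  out <- tibble::tibble(locus_id = as.character(locus_id), !!!cols)
  if (!is.null(ref)) out <- tibble::add_column(out, ref = ref, .after = "locus_id")
  if (!is.null(alt)) out <- tibble::add_column(out, alt = alt, .after = "ref")
  out
}

validate_counts <- function(totals, variants) {
  if (anyNA(totals) || anyNA(variants)) {
    stop("read counts must not contain NA", call. = FALSE)
  }
  if (any(totals < 0L) || any(variants < 0L)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  bad <- which(variants > totals)
  if (length(bad)) {
    stop("variant reads exceed total reads at ", length(bad),
         " cell(s); first offending locus row ",
         ((bad[1] - 1L) %% nrow(as.matrix(totals))) + 1L, call. = FALSE)
  }
  invisible(TRUE)
}

# split a wide count tibble into integer matrices; returns list(totals,
# variants, samples, locus_id)
counts_to_matrices <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (!"locus_id" %in% names(counts)) {
    stop("count table must have a `locus_id` column", call. = FALSE)
  }
  n_cols <- grep("_N$", names(counts), value = TRUE)
  samples <- sub("_N$", "", n_cols)
  x_cols <- paste0(samples, "_X")
  missing_x <- setdiff(x_cols, names(counts))
  if (length(n_cols) == 0L || length(missing_x)) {
    stop("count table needs paired `<sample>_N` / `<sample>_X` columns",
         call. = FALSE)
  }
  totals <- as.matrix(counts[n_cols])
  variants <- as.matrix(counts[x_cols])
  storage.mode(totals) <- "integer"
  storage.mode(variants) <- "integer"
  validate_counts(totals, variants)
  list(totals = totals, variants = variants, samples = samples,
       locus_id = as.character(counts$locus_id))
}

# parse "chrom:pos" locus ids; NA pos where not positional
parse_locus_id <- function(locus_id) {
  m <- regmatches(locus_id, regexec("^(.+):([0-9]+)$", locus_id))
  chrom <- vapply(m, function(x) if (length(x) == 3L) x[2] else NA_character_, "")
  pos <- vapply(m, function(x) if (length(x) == 3L) as.numeric(x[3]) else NA_real_, 0)
  tibble::tibble(chrom = chrom, pos = pos)
}
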