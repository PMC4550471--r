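#' Read a per-locus count table
#'
#' The count-table dialect is a TSV with header `locus_id` (optionally
#' followed by `ref` and `alt`) and then per-sample column pairs
#' `<sample>_N`, `<sample>_X`. Blank or `"."` cells are read as N = 0,
#' X = 0. Every cell is validated (non-negative, X <= N) and malformed input
#' is reported with its line number.
#'
#' @param path file path.
#' @return a wide count tibble (see [count_table()]).
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("malformed header: file is empty: ", path, call. = FALSE)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "locus_id") {
    stop("malformed header: first column must be `locus_id` (line 1)",
         call. = FALSE)
  }
  extra <- intersect(c("ref", "alt"), header)
  meta_cols <- c("locus_id", extra)
  data_cols <- setdiff(header, meta_cols)
  n_cols <- grep("_N$", data_cols, value = TRUE)
  samples <- sub("_N$", "", n_cols)
  if (length(samples) == 0L ||
      !setequal(data_cols, c(n_cols, paste0(samples, "_X")))) {
    stop("malformed header: expected `<sample>_N`/`<sample>_X` column pairs ",
         "(line 1)", call. = FALSE)
  }
  body <- lines[-1]
  cells <- strsplit(body, "\t", fixed = TRUE)
  width <- lengths(cells)
  # a trailing empty cell is dropped by strsplit; pad one short
  short <- width == length(header) - 1L
  cells[short] <- lapply(cells[short], function(x) c(x, ""))
  width[short] <- length(header)
  if (any(width != length(header))) {
    stop("ragged row at line ", which(width != length(header))[1] + 1L,
         ": expected ", length(header), " fields", call. = FALSE)
  }
  mat <- do.call(rbind, cells)
  colnames(mat) <- header
  num <- mat[, data_cols, drop = FALSE]
  num[num == "" | num == "."] <- "0"
  suppressWarnings(vals <- matrix(as.integer(num), nrow = nrow(mat)))
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1]
    stop("non-integer count at line ", bad + 1L, call. = FALSE)
  }
  colnames(vals) <- data_cols
  totals <- vals[, n_cols, drop = FALSE]
  variants <- vals[, paste0(samples, "_X"), drop = FALSE]
  if (any(vals < 0L)) {
    bad <- which(rowSums(vals < 0L) > 0)[1]
    stop("negative count at line ", bad + 1L, call. = FALSE)
  }
  over <- rowSums(variants > totals) > 0
  if (any(over)) {
    stop("variant reads exceed total reads (X > N) at line ",
         which(over)[1] + 1L, call. = FALSE)
  }
  count_table(mat[, "locus_id"], totals, variants, samples = samples,
              ref = if ("ref" %in% extra) mat[, "ref"] else NULL,
              alt = if ("alt" %in% extra) mat[, "alt"] else NULL)
}

#' Write a count table
#'
#' Inverse of [read_count_table()]; round-trips losslessly.
#'
#' @param counts a wide count tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  m <- counts_to_matrices(counts)  # validates
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Write the truth sidecar of a simulated dataset
#'
#' TSV with columns `locus_id`, `true_p`, `true_e`.
#'
#' @param truth the `truth` tibble of a [simulate_counts()] result.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(all(c("locus_id", "maf", "error_rate") %in% names(truth)))
  readr::write_tsv(tibble::tibble(locus_id = truth$locus_id,
                                  true_p = truth$maf,
                                  true_e = truth$error_rate), path)
  invisible(path)
}

#' Read a truth sidecar
#'
#' @param path file written by [write_truth()].
#' @return tibble `locus_id`, `maf`, `error_rate`.
#' @export
read_truth <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(locus_id = as.character(x$locus_id), maf = x$true_p,
                 error_rate = x$true_e)
}

#' Read a known-SNP exclusion list
#'
#' Either a 2-column TSV (`chrom`, `pos`, no header), normalized to
#' `"chrom:pos"` ids, or a 1-column list of locus ids. Duplicates are
#' removed.
#'
#' @param path file path.
#' @return character vector of locus ids.
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop("exclusion list not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (!length(lines)) return(character())
  cells <- strsplit(lines, "\t", fixed = TRUE)
  w <- lengths(cells)
  if (any(w > 2L)) {
    stop("exclusion list must have 1 (id) or 2 (chrom, pos) columns; line ",
         which(w > 2L)[1], call. = FALSE)
  }
  ids <- vapply(cells, function(x) {
    if (length(x) == 2L) paste0(x[1], ":", x[2]) else x[1]
  }, "")
  unique(ids)
}

# ---- mpileup text ---------------------------------------------------------

# parse one mpileup base column; returns per-read tibble of base (upper case,
# "." for reference match) respecting quality filtering
parse_pileup_bases <- function(bases, quals, min_base_quality, line_no) {
  out <- character()
  qual_idx <- 0L
  i <- 1L
  nb <- nchar(bases)
  qv <- utf8ToInt(quals) - 33L
  while (i <= nb) {
    ch <- substr(bases, i, i)
    if (ch == "^") {
      i <- i + 2L  # read-start marker plus mapping-quality byte
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      m <- regmatches(substr(bases, i + 1L, nb),
                      regexpr("^[0-9]+", substr(bases, i + 1L, nb)))
      if (!length(m)) {
        stop("malformed pileup at line ", line_no,
             ": indel marker without length", call. = FALSE)
      }
      i <- i + 1L + nchar(m) + as.integer(m)
    } else {
      qual_idx <- qual_idx + 1L
      keep <- qual_idx <= length(qv) && qv[qual_idx] >= min_base_quality
      up <- toupper(ch)
      if (ch %in% c(".", ",")) {
        if (keep) out <- c(out, ".")
      } else if (up %in% c("A", "C", "G", "T")) {
        if (keep) out <- c(out, up)
      } else if (up %in% c("*", "N", ">", "<")) {
        # deletions, unknowns and reference skips carry no allele information
      } else {
        stop("unknown base character '", ch, "' in pileup at line ", line_no,
             call. = FALSE)
      }
      i <- i + 1L
    }
  }
  out
}

#' Convert samtools mpileup text into a count table
#'
#' Parses multi-sample `samtools mpileup` output (one `depth, bases,
#' qualities` column triple per sample). Per locus the variant allele is the
#' most frequent non-reference base pooled over all samples (ties broken in
#' A < C < G < T order); per sample, N counts reference-matching plus
#' variant-allele reads and X the variant-allele reads. Reads of other
#' non-reference bases are excluded from both, keeping the biallelic model
#' honest, and bases below `min_base_quality` (Phred, default 13) are
#' dropped. Strand case is pooled.
#'
#' @param path mpileup text file (or connection).
#' @param min_base_quality minimum Phred base quality.
#' @param samples optional sample names (default `S1..Sn`).
#' @return a wide count tibble with `ref` and `alt` columns and
#'   `locus_id = "chrom:pos"`.
#' @export
read_pileup_counts <- function(path, min_base_quality = 13, samples = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty pileup input", call. = FALSE)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  w <- lengths(rows)
  if (any((w - 3L) %% 3L != 0L | w < 6L)) {
    stop("malformed pileup at line ", which((w - 3L) %% 3L != 0L | w < 6L)[1],
         ": expected chrom, pos, ref plus per-sample triples", call. = FALSE)
  }
  n <- (w[1] - 3L) %/% 3L
  if (any(w != w[1])) {
    stop("malformed pileup at line ", which(w != w[1])[1],
         ": inconsistent sample count", call. = FALSE)
  }
  J <- length(rows)
  totals <- matrix(0L, J, n)
  variants <- matrix(0L, J, n)
  ids <- character(J)
  refs <- character(J)
  alts <- character(J)
  for (j in seq_len(J)) {
    r <- rows[[j]]
    ids[j] <- paste0(r[1], ":", r[2])
    ref <- toupper(r[3])
    refs[j] <- ref
    per_sample <- vector("list", n)
    for (s in seq_len(n)) {
      per_sample[[s]] <- parse_pileup_bases(r[3L + 3L * s - 1L],
                                            r[3L + 3L * s],
                                            min_base_quality, j)
    }
    pooled <- unlist(per_sample)
    nonref <- pooled[pooled != "." & pooled != ref]
    if (length(nonref)) {
      tab <- table(factor(nonref, levels = c("A", "C", "G", "T")))
      alt <- names(tab)[which.max(tab)]  # which.max keeps A<C<G<T on ties
    } else {
      alt <- NA_character_
    }
    alts[j] <- alt
    for (s in seq_len(n)) {
      b <- per_sample[[s]]
      n_ref <- sum(b == "." | b == ref)
      n_alt <- if (is.na(alt)) 0L else sum(b == alt)
      totals[j, s] <- n_ref + n_alt
      variants[j, s] <- n_alt
    }
  }
  count_table(ids, totals, variants, samples = samples, ref = refs, alt = alts)
}

# ---- call output ----------------------------------------------------------

#' Write SNP calls
#'
#' TSV format: `locus_id`, `statistic`, `p_value`, `q_value`, `called` (plus
#' `ref`/`alt` when available). VCF format: VCFv4.2 site records for
#' positional loci (`locus_id = "chrom:pos"`), QUAL = -10 log10(p) capped at
#' 9999, INFO keys `ELRT`, `PV`, `QV`, FILTER `PASS` iff called, with the
#' fitted null parameters and nominal FDR recorded as header meta lines.
#' VCF records are sorted by (chrom, pos).
#'
#' @param x a `snp_calls` object from [call_snps()], or its `calls` tibble
#'   (then `null` and `fdr` should be given).
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param null an `elrt_null` (taken from `x` when it is a `snp_calls`).
#' @param fdr nominal FDR level for the header.
#' @param ref,alt optional allele vectors overriding columns of the calls.
#' @return `path`, invisibly.
#' @export
write_calls <- function(x, path, format = c("tsv", "vcf"), null = NULL,
                        fdr = NULL, ref = NULL, alt = NULL) {
  format <- match.arg(format)
  if (inherits(x, "snp_calls")) {
    calls <- x$calls
    if (is.null(null)) null <- x$null
    if (is.null(fdr)) fdr <- x$nominal_fdr
  } else {
    calls <- x
  }
  if (!is.null(ref)) calls$ref <- ref
  if (!is.null(alt)) calls$alt <- alt
  if (format == "tsv") {
    keep <- intersect(c("locus_id", "ref", "alt", "statistic", "p_value",
                        "q_value", "called"), names(calls))
    readr::write_tsv(calls[keep], path)
    return(invisible(path))
  }
  pos <- parse_locus_id(calls$locus_id)
  if (anyNA(pos$pos)) {
    stop("VCF output requires positional loci (`chrom:pos` ids); ",
         sum(is.na(pos$pos)), " loci are not positional", call. = FALSE)
  }
  ord <- order(pos$chrom, pos$pos)
  calls <- calls[ord, ]; pos <- pos[ord, ]
  qual <- pmin(-10 * log10(pmax(calls$p_value, 1e-1000)), 9999)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=elrtcall_", as.character(utils::packageVersion("elrtcall"))),
    if (!is.null(null)) sprintf("##elrtcall_null=<a=%.6g,k=%.6g>", null$a, null$k),
    if (!is.null(fdr)) sprintf("##elrtcall_nominal_fdr=%g", fdr),
    "##INFO=<ID=ELRT,Number=1,Type=Float,Description=\"Estimated likelihood-ratio test statistic\">",
    "##INFO=<ID=PV,Number=1,Type=Float,Description=\"p-value under the fitted mixture null\">",
    "##INFO=<ID=QV,Number=1,Type=Float,Description=\"Benjamini-Hochberg adjusted p-value\">",
    "##FILTER=<ID=notCalled,Description=\"q-value above the nominal FDR level\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ref_col <- if ("ref" %in% names(calls)) calls$ref else rep("N", nrow(calls))
  alt_col <- if ("alt" %in% names(calls)) calls$alt else rep(".", nrow(calls))
  alt_col[is.na(alt_col)] <- "."
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%.4g\t%s\tELRT=%.6g;PV=%.6g;QV=%.6g",
                  pos$chrom, as.integer(pos$pos), calls$locus_id, ref_col,
                  alt_col, qual, ifelse(calls$called, "PASS", "notCalled"),
                  calls$statistic, calls$p_value, calls$q_value)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a TSV call file
#'
#' @param path file written by [write_calls()] with `format = "tsv"`.
#' @return tibble of call records.
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(locus_id = "c"))
}
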