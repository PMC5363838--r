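# Omics normalizations: per-ORF transcriptional activity within a genome
# bin, and functional-gene counts normalized to the single-copy marker
# rpoBC.

#' Validate a per-ORF count table
#'
#' @param df data.frame with columns `orf_id`, `bin_id`, `length` (bp, > 0)
#'   and `count` (reads, >= 0); an optional `family` column tags gene
#'   families (pflAB, bd_I, bd_II, heme_copper_oxidase, dsrAB, nirS,
#'   rpoBC).
#' @return The validated data.frame, classed `count_table`.
#' @export
count_table <- function(df) {
  need <- c("orf_id", "bin_id", "length", "count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("count table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$orf_id))
    stop("duplicate orf_id(s): ",
         paste(unique(df$orf_id[duplicated(df$orf_id)]), collapse = ", "))
  if (any(df$length <= 0)) stop("ORF lengths must be positive")
  if (any(df$count < 0)) stop("read counts must be non-negative")
  class(df) <- c("count_table", "data.frame")
  df
}

#' Per-ORF transcriptional activity within each genome bin
#'
#' activity = (count / length) / (bin total count / bin total length), so
#' that 1.0 is the average transcriptional activity of the bin: the
#' ORF-length-weighted mean activity within each bin is exactly 1.
#'
#' @param counts A [count_table] (or coercible data.frame).
#' @return The table with an added `activity` column; bins with zero total
#'   reads are dropped with a warning.
#' @examples
#' ct <- count_table(data.frame(orf_id = c("o1", "o2"), bin_id = "A",
#'                              length = c(1000, 1000), count = c(30, 10)))
#' transcriptional_activity(ct)$activity  # 1.5, 0.5
#' @export
transcriptional_activity <- function(counts) {
  ct <- count_table(as.data.frame(counts))
  tot_count <- tapply(ct$count, ct$bin_id, sum)
  empty <- names(tot_count)[tot_count == 0]
  if (length(empty)) {
    warning("bin(s) with zero total reads skipped: ",
            paste(empty, collapse = ", "))
    ct <- ct[!ct$bin_id %in% empty, , drop = FALSE]
    tot_count <- tot_count[setdiff(names(tot_count), empty)]
  }
  if (!nrow(ct)) stop("no bin has any reads")
  tot_len <- tapply(ct$length, ct$bin_id, sum)
  bin_mean <- tot_count[as.character(ct$bin_id)] / tot_len[as.character(ct$bin_id)]
  ct$activity <- (ct$count / ct$length) / as.numeric(bin_mean)
  count_table(ct)
}

#' Normalize functional-gene counts to the rpoBC marker
#'
#' Read counts per gene family divided by the count of the conserved
#' single-copy RNA-polymerase gene rpoBC, giving per-genome-equivalent
#' abundances (metagenome) or activities (transcriptome).
#'
#' @param family_counts Named numeric vector of reads per gene family.
#' @param rpoBC_count rpoBC read count (> 0).
#' @param sum_bd If `TRUE`, also report `bd` as the sum of the `bd_I` and
#'   `bd_II` families when both are present.
#' @return Named numeric vector of normalized abundances.
#' @examples
#' normalize_to_rpoBC(c(nirS = 50), rpoBC_count = 200)  # 0.25
#' @export
normalize_to_rpoBC <- function(family_counts, rpoBC_count, sum_bd = FALSE) {
  if (length(rpoBC_count) != 1L || is.na(rpoBC_count) || rpoBC_count <= 0)
    stop("normalizer absent: rpoBC count must be a single positive number")
  if (!length(family_counts)) return(setNames(numeric(0), character(0)))
  stopifnot(is.numeric(family_counts), !is.null(names(family_counts)))
  out <- family_counts / rpoBC_count
  if (sum_bd && all(c("bd_I", "bd_II") %in% names(out)))
    out["bd"] <- out["bd_I"] + out["bd_II"]
  out
}

#' rpoBC normalization from a tagged count table
#'
#' Sums reads per `family` tag and normalizes against the `rpoBC` family.
#'
#' @param counts A [count_table] with a `family` column.
#' @param sum_bd Passed to [normalize_to_rpoBC()].
#' @return Named numeric vector (rpoBC itself reported as 1).
#' @export
normalize_families <- function(counts, sum_bd = FALSE) {
  ct <- count_table(as.data.frame(counts))
  if (is.null(ct$family)) stop("count table has no 'family' column")
  fam <- ct[!is.na(ct$family) & nzchar(ct$family), ]
  s <- tapply(fam$count, fam$family, sum)
  sums <- setNames(as.numeric(s), names(s))
  if (!"rpoBC" %in% names(sums)) stop("normalizer absent: no rpoBC reads")
  normalize_to_rpoBC(sums[names(sums) != "rpoBC"], sums[["rpoBC"]],
                     sum_bd = sum_bd)
}
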