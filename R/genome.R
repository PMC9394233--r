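#' hg19 chromosome lengths
#'
#' Lengths in base pairs of the 24 human reference chromosomes (hg19 /
#' GRCh37, UCSC naming), the coordinate system used for 100-kb bin
#' profiling of single cells.
#'
#' @param chroms Character vector of chromosome names to return, in the
#'   order wanted. Defaults to chr1-chr22, chrX, chrY.
#' @return Named numeric vector of chromosome lengths (bp).
#' @examples
#' sum(ceiling(hg19_chrom_lengths() / 1e5)) # total 100-kb bins
#' @export
hg19_chrom_lengths <- function(chroms = paste0("chr", c(1:22, "X", "Y"))) {
  len <- c(
    chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566
  )
  missing <- setdiff(chroms, names(len))
  if (length(missing) > 0) {
    abort(paste0("unknown hg19 chromosome(s): ", paste(missing, collapse = ", ")))
  }
  len[chroms]
}

# UCSC hg19 gap-track centromere coordinates (0-based starts).
.hg19_centromeres <- function() {
  tibble(
    chrom = paste0("chr", c(1:22, "X", "Y")),
    cen_start = c(
      121535434, 92326171, 90504854, 49660117, 46405641, 58830166,
      58054331, 43838887, 47367679, 39254935, 51644205, 34856694,
      16000000, 16000000, 17000000, 35335801, 22263006, 15460898,
      24681782, 26369569, 11288129, 13000000, 58632012, 10104553
    ),
    cen_end = c(
      124535434, 95326171, 93504854, 52660117, 49405641, 61830166,
      61054331, 46838887, 50367679, 42254935, 54644205, 37856694,
      19000000, 19000000, 20000000, 38335801, 25263006, 18460898,
      27681782, 29369569, 14288129, 16000000, 61632012, 13104553
    )
  )
}

#' Chromosome-arm intervals for hg19
#'
#' Splits each hg19 chromosome at its centromere into p and q arms. The
#' arm table is the coordinate input for arm-level read aggregation and
#' for the arm-distribution QC statistic.
#'
#' @return Tibble with columns `chrom`, `start`, `end` (0-based,
#'   half-open) and `arm` (e.g. `"1p"`, `"Xq"`); 48 rows.
#' @export
hg19_arms <- function() {
  len <- hg19_chrom_lengths()
  cen <- .hg19_centromeres()
  short <- sub("^chr", "", cen$chrom)
  bind_rows(
    tibble(chrom = cen$chrom, start = 0, end = cen$cen_start,
           arm = paste0(short, "p")),
    tibble(chrom = cen$chrom, start = cen$cen_end,
           end = unname(len[cen$chrom]), arm = paste0(short, "q"))
  ) %>%
    arrange(match(.data$chrom, cen$chrom), .data$start)
}

#' Chromosome arms excluded from the arm-distribution QC
#'
#' Acrocentric p arms carry few mappable repeat-derived reads and the sex
#' chromosomes differ between donors, so these arms are dropped before
#' distribution ratios are formed: 13p, 14p, 15p, 21p, 22p, Xp, Xq, Yp, Yq.
#'
#' @return Character vector of arm labels.
#' @export
default_excluded_arms <- function() {
  c("13p", "14p", "15p", "21p", "22p", "Xp", "Xq", "Yp", "Yq")
}
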