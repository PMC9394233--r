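#' Benchmark tables from the pipeline optimization experiments
#'
#' Small built-in measurement tables from the wet-lab optimization of the
#' single-cell WGA + library-preparation pipeline, used to exercise the
#' method-comparison statistics on real numbers.
#'
#' * `wga_library_yields()`: library yields (nM) of 24 WGA products
#'   (single and pooled leukocytes and MCF-7 breast-cancer cells, plus
#'   controls) prepared both with a PCR-free protocol (`yield_truseq`)
#'   and a low-pass protocol (`yield_lowpass`; one unamplified genomic
#'   control has no low-pass library and is `NA`).
#' * `leukocyte_mads()`: genome-wide MAD noise of 11 leukocyte samples
#'   under the two library preparations.
#' * `mcf7_wga_mads()`: chromosome-2 MAD noise of MCF-7 samples
#'   amplified with a PCR-based WGA (`mad_ampli1`) versus a
#'   multiple-displacement WGA (`mad_replig`; failed or unavailable
#'   reactions are `NA`).
#'
#' @return A tibble.
#' @name benchmarks
NULL

#' @rdname benchmarks
#' @export
wga_library_yields <- function() {
  tibble(
    sample_no = 1:24,
    sample_name = c(
      "Leuko 1A", "Leuko 1B", "Leuko 1C", "Leuko 1D", "Leuko 2A", "Leuko 2B",
      "Leuko 5A", "Leuko 5B", "Leuko 10A", "Leuko 10B", "MCF7 1A", "MCF7 1B",
      "MCF7 1C", "MCF7 2A", "MCF7 2B", "MCF7 5", "MCF7 10", "Leuko QC6",
      "MCF7 QC6", "MCF7 QC5", "VyCAP Ctrl 1", "VyCAP Ctrl 2", "MCF7 Ampli1",
      "MCF7 Genomic"
    ),
    yield_truseq = c(4.7, 3.0, 5.3, 6.9, 5.3, 7.9, 8.3, 4.9, 4.0, 3.5, 3.6,
                     4.9, 4.9, 4.3, 2.4, 6.6, 5.1, 8.1, 1.9, 1.4, 4.3, 3.4,
                     1.4, 0.2),
    yield_lowpass = c(45.8, 19.2, 82.8, 123.1, 53.2, 47.0, 75.1, 83.9, 23.1,
                      7.3, 22.4, 7.0, 101.3, 82.3, 65.5, 4.8, 24.7, 55.3,
                      80.2, 25.9, 5.8, 93.7, 15.5, NA)
  )
}

#' @rdname benchmarks
#' @export
leukocyte_mads <- function() {
  tibble(
    sample_no = c(1:10, 18),
    sample_name = c("Leuko 1A", "Leuko 1B", "Leuko 1C", "Leuko 1D",
                    "Leuko 2A", "Leuko 2B", "Leuko 5A", "Leuko 5B",
                    "Leuko 10A", "Leuko 10B", "Leuko QC6"),
    mad_truseq = c(0.198, 0.194, 0.220, 0.277, 0.237, 0.255, 0.236, 0.201,
                   0.295, 0.216, 0.219),
    mad_lowpass = c(0.169, 0.162, 0.214, 0.244, 0.235, 0.236, 0.226, 0.217,
                    0.296, 0.226, 0.223)
  )
}

#' @rdname benchmarks
#' @export
mcf7_wga_mads <- function() {
  tibble(
    sample_no = c(11:17, 24),
    sample_name = c("MCF7 1A", "MCF7 1B", "MCF7 1C", "MCF7 2A", "MCF7 2B",
                    "MCF7 5", "MCF7 10", "MCF7 Genomic"),
    mad_ampli1 = c(0.292, 0.292, 0.240, 0.260, 0.260, 0.266, 0.241, 0.062),
    mad_replig = c(0.769, 0.534, NA, 0.763, NA, 1.114, 0.286, 0.107)
  )
}
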