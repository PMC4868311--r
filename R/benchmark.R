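#' Benchmark antibody set
#'
#' The 28 apo human/humanized antibody crystal structures used to benchmark
#' bulged torso restraints, with their HCDR3 loop lengths (11 to 26
#' residues, mean 16 -- the repertoire-typical HCDR3 length) and crystal
#' resolutions.  All HCDR3 residues are resolved in each structure.
#'
#' @return data.frame with columns `pdb_id`, `hcdr3_length`,
#'   `resolution` (Angstrom) and `source`.
#' @export
benchmark_antibodies <- function() {
  data.frame(
    pdb_id = c("1WT5", "2G75", "4G5Z", "3QRG", "4G6K", "4LLU", "1FVC",
               "3HI5", "4HFW", "4FQH", "4NM4", "8FAB", "3G6A", "3TNM",
               "3W9D", "1AQK", "1DQL", "1OM3", "1U6A", "3AAZ", "4M5Y",
               "3INU", "3QEH", "4F58", "1HZH", "4LKC", "1RHH", "4FNL"),
    hcdr3_length = c(11L, 11L, 11L, 12L, 12L, 12L, 13L, 13L, 13L, 14L,
                     14L, 14L, 15L, 15L, 15L, 16L, 16L, 16L, 17L, 17L,
                     17L, 18L, 18L, 18L, 20L, 22L, 24L, 26L),
    resolution = c(2.10, 2.28, 1.83, 1.70, 1.90, 2.16, 2.20, 2.50, 2.60,
                   2.05, 2.65, 1.80, 2.10, 1.85, 2.32, 1.84, 2.60, 2.20,
                   2.81, 2.20, 1.55, 2.50, 2.59, 2.49, 2.70, 2.20, 1.90,
                   2.30),
    source = c("Humanized", "Human", "Human", "Human", "Humanized",
               "Human", "Humanized", "Human", "Human", "Human", "Human",
               "Human", "Human", "Human", "Human", "Human", "Human",
               "Human", "Human", "Humanized", "Human", "Human", "Human",
               "Human", "Human", "Human", "Human", "Human"),
    stringsAsFactors = FALSE)
}
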