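# Shared study configuration for the analysis drivers.
#
# Three libraries mirror a control/low-dose/high-dose TSA design (T0, T1,
# T2.5). Depth is a scaled-down stand-in for the multi-million-tag real
# libraries so every driver runs in seconds; all other knobs are the
# generator defaults discussed in the methods vignette.

library(tagdge)

STUDY_SEED <- 2016L
DATA_DIR <- "results/data"
OUT_DIR <- "results"

study_synthetic_config <- function() {
  synthetic_config(
    n_genes = 1000,
    transcript_length_range = c(300, 3000),
    n_libraries = 3,
    library_depth = 200000,
    dispersion = 0.1,
    de_fraction = 0.1,
    de_fold_changes = c(0.25, 0.5, 2, 4),
    error_rate = 0.005,
    seed = STUDY_SEED)
}

LIB_NAMES <- c("T0", "T1", "T2.5")

lib_file <- function(prefix, lib, ext = "tsv") {
  file.path(DATA_DIR, sprintf("%s_%s.%s", prefix, lib, ext))
}
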