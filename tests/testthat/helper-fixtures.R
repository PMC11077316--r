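# A small synthetic scenario shared across test files (computed once per
# test run): 3 WBR, 2 HRA, 2 LRA and 1 confirmation species, 30 background,
# 4 planted candidate and 3 paralog families.

.fixtures <- new.env(parent = emptyenv())

small_specs <- function() {
  c(lapply(1:3, function(i) species_spec(paste0("wbr", i), "WBR", 30, 0.1)),
    lapply(1:2, function(i) species_spec(paste0("hra", i), "HRA", 30, 0.1)),
    lapply(1:2, function(i) species_spec(paste0("lra", i), "LRA", 30, 0.1)),
    list(species_spec("conf1", "CONFIRM", 30, 0.1)))
}

small_scenario <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulate_species_set(small_specs(), n_cbr = 4,
                                          n_paralog = 3, seed = 7)
  .fixtures$sim
}

small_config <- function() {
  screen_config(wbr = paste0("wbr", 1:3), hra = paste0("hra", 1:2),
                lra = paste0("lra", 1:2), confirm = "conf1")
}

small_screen <- function() {
  if (is.null(.fixtures$screen))
    .fixtures$screen <- run_screen(small_scenario()$proteomes, small_config())
  .fixtures$screen
}

fixture_pwms <- function() {
  if (is.null(.fixtures$pwms))
    .fixtures$pwms <- read_jaspar(
      system.file("extdata", "synthetic_pfms.jaspar", package = "regenscreen"),
      system.file("extdata", "synthetic_pfm_classes.tsv",
                  package = "regenscreen"))
  .fixtures$pwms
}
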