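# Small in-code fixtures shared across test files.

tiny_library <- function() {
  GuideLibrary(data.frame(
    guide_id = c("g1", "g2", "g3"),
    target_id = c("Oct4", "Oct4", "NT"),
    target_class = c("tf", "tf", "nontargeting")))
}

tiny_sheet <- function(screen_id = "s", populations = c("high", "low"),
                       replicates = 1) {
  grid <- expand.grid(population = populations,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  SampleSheet(data.frame(
    sample_id = paste0(screen_id, "_", grid$population, "_r", grid$replicate),
    screen_id = screen_id, population = grid$population,
    replicate = grid$replicate))
}

random_library <- function(n_tf = 20, gpt = 4, n_nt = 10, seed = 1) {
  generateLibrary(n_tf, gpt, n_nt, seed = seed)
}

# Guide-statistics data.frame with a prescribed z vector (one replicate).
fake_guide_stats <- function(library, z, replicate = 1, screen_id = "s",
                             comparison = "high_vs_low") {
  data.frame(guide_id = guideIds(library), screen_id = screen_id,
             replicate = replicate, comparison = comparison,
             log2fc = z, z = z)
}
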