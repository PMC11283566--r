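# small in-code fixtures shared across tests

toy_counts <- function(m, samples = NULL, taxa = NULL) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- taxa %||% sprintf("t%d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_metadata <- function(sample_ids, is_control = rep(FALSE, length(sample_ids)),
                         planted = "planted", drought = "watered", day = 2) {
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids,
             crop = ifelse(is_control, NA, "bean"),
             planted = ifelse(is_control, NA, rep_len(planted, n)),
             drought = ifelse(is_control, NA, rep_len(drought, n)),
             day = ifelse(is_control, NA, rep_len(day, n)),
             replicate = ifelse(is_control, NA, seq_len(n)),
             is_negative_control = is_control,
             stringsAsFactors = FALSE)
}

# a tiny, fast simulation configuration for property tests
small_config <- function(seed = 1, ...) {
  simulation_config(n_taxa = 120, crops = "bean", days = c(2, 4),
                    n_replicates = 3, depth_mean = 4000,
                    n_contaminants = 3, n_controls = 5,
                    n_responder_taxa = 10, rng_seed = seed, ...)
}

# independent Bray-Curtis formula, used as an oracle
bray_formula <- function(x, y) 1 - 2 * sum(pmin(x, y)) / sum(x + y)
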