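# shared fixtures for the statistical and pipeline tests

# wrap a plain feature matrix as a feature_table
make_feature_table <- function(X, grasp_ids, repetition = 1L,
                               subject = "t01", modality = "emg",
                               family = "RMS", window_length = nrow(X)) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  out <- cbind(data.frame(grasp_id = as.integer(grasp_ids),
                          repetition = as.integer(repetition)),
               as.data.frame(X))
  structure(out, class = c("feature_table", "data.frame"),
            subject_id = subject, modality = modality, family = family,
            window_length = window_length)
}

# small grasp sets
gs4 <- grasp_set(1:4, c("A", "B", "C", "D"))
gs8 <- grasp_set(1:8, LETTERS[1:8])

# a fast cohort configuration for pipeline tests: short movements, few
# repetitions, default noise structure
tiny_synth_config <- function(n_subjects = 2L, grasp_set = gs4, seed = 42L, ...) {
  synth_config(n_subjects = n_subjects, grasp_set = grasp_set,
               n_repetitions = 2L, movement_s = 1, rest_s = 1,
               seed = seed, ...)
}
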