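# Desk-scale domain-shift study shared by the acceptance tests.  Built
# lazily once per test session and cached; sizes match the package's
# documented desk-scale protocol (see the methods vignette).

study_cache <- new.env(parent = emptyenv())

desk_study_config <- function() {
  study_config(
    kind = "domain_shift",
    n_train = 12000, n_validation = 1500, n_test = 2500,
    methods = c("ho_direct", "conv_lg", "ae_task"),
    ae = list(channel_counts = 20, learning_rates = c(1e-3, 5e-3),
              epochs = 100, batch_size = 250, train_pairs = 8001,
              burn_in = FALSE),
    lg = list(widths = c(10, 15, 20, 25, 30, 40, 50), max_channels = 10),
    bootstrap_reps = 0,
    seed = 20260921)
}

desk_study <- function() {
  if (!is.null(study_cache$out)) return(study_cache$out)
  cells <- data.frame(
    source = c("1", "1", "1", "2", "4", "4", "amalg"),
    method = c("ho_direct", "conv_lg", "ae_task", "ho_direct",
               "ho_direct", "ae_task", "ae_task"))
  out <- run_domain_shift(desk_study_config(), cells = cells, lean = TRUE)
  out$datasets <- NULL
  gc(FALSE)
  study_cache$out <- out
  out
}

study_auc <- function(out, source, method, target) {
  r <- out$results
  r$auc_binormal[r$source == source & r$method == method &
                   r$target == target]
}
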