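# Shared fixtures, all generated in code.

# Small category library + drawings for classifier tests.
tiny_library <- function(n = 8, n_animate = 4, seed = 11) {
  generate_category_library(n, n_animate, seed = seed)
}

make_drawings <- function(library, per_category = 6, ages = 2:10,
                          seed = 21, model = age_model()) {
  draws <- list()
  set.seed(seed)
  for (ci in seq_along(library)) {
    for (k in seq_len(per_category)) {
      draws[[length(draws) + 1]] <- generate_drawing(
        library[[ci]], sample(ages, 1), model,
        seed = seed + 1000 * ci + k)
    }
  }
  draws
}

targets_of <- function(draws) vapply(draws, `[[`, character(1), "category")

# Hand-built classifier outputs with a prescribed confusion rule: the
# predicted category of each misclassified drawing is drawn from `confuser`.
fake_outputs <- function(meta, per_category = 20, confuser, seed = 1) {
  set.seed(seed)
  cats <- meta$category
  rows <- list()
  for (tg in cats) {
    for (k in seq_len(per_category)) {
      pred <- confuser(tg, cats)
      rows[[length(rows) + 1]] <- tibble::tibble(
        drawing_id = paste0(tg, "_", k), target = tg, predicted = pred,
        correct = pred == tg)
    }
  }
  dplyr::bind_rows(rows)
}

# Constructed 4AFC log that loses exactly the planted counts at each
# exclusion stage; provided by the package.
build_exclusion_fixture <- function() demo_exclusion_log()
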