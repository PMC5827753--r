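new_group_spec <- function(task, n_trustworthy, n_concerning, key) {
  nm <- feature_names()
  key <- as_tibble(key)
  stopifnot(all(key$feature %in% nm))
  # non-key features: identical group means, field-plausible scales
  base_mean <- rep(0.5, length(nm))
  base_sd <- rep(0.10, length(nm))
  names(base_mean) <- names(base_sd) <- nm
  base_mean[paste0("ML_", names(system_parcellation()))] <- 50
  base_sd[paste0("ML_", names(system_parcellation()))] <- 10
  base_mean["SA"] <- 20; base_sd["SA"] <- 5
  base_mean["CT"] <- 1800; base_sd["CT"] <- 300
  base_mean["MW"] <- 0.6; base_sd["MW"] <- 0.15
  base_mean["E"] <- 0.5; base_sd["E"] <- 0.15
  base_mean["AI"] <- 0; base_sd["AI"] <- 0.1
  tab <- tibble(
    feature = nm,
    mean_trustworthy = unname(base_mean), sd_trustworthy = unname(base_sd),
    mean_concerning = unname(base_mean), sd_concerning = unname(base_sd),
    key = FALSE
  )
  i <- match(key$feature, tab$feature)
  tab$mean_trustworthy[i] <- key$mean_t
  tab$sd_trustworthy[i] <- pmax(key$se_t, 0.005) * sqrt(n_trustworthy)
  tab$mean_concerning[i] <- key$mean_c
  tab$sd_concerning[i] <- pmax(key$se_c, 0.005) * sqrt(n_concerning)
  tab$key[i] <- TRUE
  structure(
    list(task = task, n_trustworthy = n_trustworthy,
         n_concerning = n_concerning, table = tab,
         key_features = key$feature),
    class = "group_spec"
  )
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("<group_spec> task %s: %d trustworthy / %d concerning\n",
              x$task, x$n_trustworthy, x$n_concerning))
  cat("  key features:", paste(x$key_features, collapse = ", "), "\n")
  invisible(x)
}

#' Two-group feature specifications for the two surgical tasks
#'
#' Encode the published group summaries (mean, standard error of the
#' mean) of the discriminative features for the simple urethrovesical
#' anastomosis task (UVA: 63 trustworthy / 24 concerning recordings,
#' three gamma-band functional key features) and the complex lymph node
#' dissection task (LND: 43 / 40, seven gamma-band functional features
#' plus blink rate and asymmetry index). Standard deviations are
#' recovered from standard errors as SD = SE * sqrt(N); a printed SE of
#' 0.00 (below reporting precision) is floored at 0.005, half the last
#' printed digit. All other features get identical group means, so only
#' the key features carry class information. Between-system pair names
#' are normalized to canonical system order (e.g. the prefrontal-frontal
#' communication is `"gamma:F-PF"`).
#'
#' @return a `group_spec` object: group sizes plus a per-feature table of
#'   group means and SDs with the key features flagged.
#' @examples
#' uva_group_spec()
#' @export
uva_group_spec <- function() {
  new_group_spec(
    task = "UVA", n_trustworthy = 63, n_concerning = 24,
    key = tibble(
      feature = c("gamma:F", "gamma:F-Pa", "gamma:F-C"),
      mean_t = c(0.37, 0.35, 0.35), se_t = c(0.01, 0.01, 0.01),
      mean_c = c(0.75, 0.58, 0.68), se_c = c(0.03, 0.03, 0.03)
    )
  )
}

#' @rdname uva_group_spec
#' @export
lnd_group_spec <- function() {
  new_group_spec(
    task = "LND", n_trustworthy = 43, n_concerning = 40,
    key = tibble(
      feature = c("gamma:F", "gamma:F-PF", "gamma:PF-Pa", "gamma:F-Pa",
                  "gamma:T-O", "gamma:F-C", "gamma:F-O", "BR", "AI"),
      mean_t = c(0.34, 0.42, 0.55, 0.38, 0.49, 0.38, 0.48, 0.83, -0.23),
      se_t   = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.02, 0.00, 0.02, 0.03),
      mean_c = c(0.73, 0.73, 0.79, 0.68, 0.74, 0.73, 0.73, 0.71, -0.10),
      se_c   = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02)
    )
  )
}

#' Simulate a feature-level two-group dataset
#'
#' Draws independent Gaussian samples per feature and group at the spec's
#' means and SDs, clips each feature to its legal range (functional
#' features and rates to \[0, 1\], AI to \[-1, 1\], power and time
#' features to non-negative) and returns a labelled feature table. An
#' optional correlation matrix over a subset of features induces
#' dependence via a Gaussian copula-style multivariate draw (useful for
#' emulating reported key-feature correlations); by default features are
#' independent because no covariance structure is published. Output is
#' fully determined by `(spec, seed)`.
#'
#' @param spec a [uva_group_spec()] / [lnd_group_spec()] style object.
#' @param seed integer seed.
#' @param n_trustworthy,n_concerning optional group-size overrides.
#' @param cor_matrix optional symmetric correlation matrix with
#'   dimnames naming a subset of features.
#' @return tibble: `recording_id`, `task`, `label` (factor
#'   concerning/trustworthy) and the 96 canonical feature columns.
#' @examples
#' d <- sim_feature_dataset(uva_group_spec(), seed = 1)
#' dplyr::count(d, label)
#' @export
sim_feature_dataset <- function(spec, seed,
                                n_trustworthy = spec$n_trustworthy,
                                n_concerning = spec$n_concerning,
                                cor_matrix = NULL) {
  stopifnot(inherits(spec, "group_spec"))
  set.seed(seed)
  rng <- feature_ranges()
  draw_group <- function(n, means, sds) {
    p <- length(means)
    if (is.null(cor_matrix)) {
      m <- matrix(rnorm(n * p), n, p)
      m <- sweep(sweep(m, 2, sds, "*"), 2, means, "+")
    } else {
      cn <- colnames(cor_matrix)
      stopifnot(!is.null(cn), all(cn %in% spec$table$feature))
      m <- matrix(rnorm(n * p), n, p)
      idx <- match(cn, spec$table$feature)
      z <- MASS::mvrnorm(n, mu = rep(0, length(cn)), Sigma = cor_matrix)
      m[, idx] <- z
      m <- sweep(sweep(m, 2, sds, "*"), 2, means, "+")
    }
    m <- pmin(pmax(m, matrix(rng$lo, n, p, byrow = TRUE)),
              matrix(rng$hi, n, p, byrow = TRUE))
    colnames(m) <- spec$table$feature
    as_tibble(m)
  }
  gt <- draw_group(n_trustworthy, spec$table$mean_trustworthy,
                   spec$table$sd_trustworthy)
  gc <- draw_group(n_concerning, spec$table$mean_concerning,
                   spec$table$sd_concerning)
  out <- bind_rows(gt, gc)
  dplyr::bind_cols(
    tibble(recording_id = sprintf("%s_%03d", spec$task, seq_len(nrow(out))),
           task = spec$task,
           label = factor(rep(c("trustworthy", "concerning"),
                              c(n_trustworthy, n_concerning)),
                          levels = c("concerning", "trustworthy"))),
    out
  )
}
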