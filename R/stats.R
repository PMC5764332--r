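#' Pairwise Pearson correlations
#'
#' Pearson r with two-sided t-test p-values for each (x, y) variable pair.
#' Pairs in which either variable has zero variance are flagged and skipped
#' (r and p set to NA).
#'
#' @param table data frame (e.g. a cohort table).
#' @param vars_x,vars_y character vectors of column names.
#' @return Tibble with `x`, `y`, `r`, `p_value`, `n`, `skipped`.
#' @export
pairwise_correlations <- function(table, vars_x, vars_y = vars_x) {
  miss <- setdiff(c(vars_x, vars_y), names(table))
  if (length(miss) > 0) {
    abort(paste0("unknown column(s): ", paste(miss, collapse = ", ")),
          class = "pw_stats_error")
  }
  grid <- tidyr::expand_grid(x = vars_x, y = vars_y)
  purrr::pmap_dfr(grid, function(x, y) {
    a <- table[[x]]; b <- table[[y]]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    n <- length(a)
    if (n < 3) abort(sprintf("fewer than 3 complete cases for (%s, %s)", x, y),
                     class = "pw_stats_error")
    if (sd(a) == 0 || sd(b) == 0 || x == y) {
      skipped <- sd(a) == 0 || sd(b) == 0
      return(tibble(x = x, y = y,
                    r = if (skipped) NA_real_ else 1,
                    p_value = NA_real_, n = n, skipped = skipped))
    }
    ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
    tibble(x = x, y = y, r = unname(ct$estimate), p_value = ct$p.value,
           n = n, skipped = FALSE)
  })
}

#' Rank-based group difference test
#'
#' Paired mode: two-sided Wilcoxon signed-rank test with continuity
#' correction (exact null enumeration for small samples). Unpaired mode:
#' Wilcoxon rank-sum (provided because between-sex comparisons are
#' independent groups; the paired variant mirrors the within-subject
#' comparisons).
#'
#' @param a,b numeric samples (equal length in paired mode).
#' @param mode `"unpaired"` (default) or `"paired"`.
#' @param exact_n_max largest sample size for which the exact null
#'   distribution is enumerated; larger samples use the normal approximation
#'   with continuity correction.
#' @return Tibble with `statistic`, `p_value`, `method`, `n`.
#' @export
group_difference_test <- function(a, b, mode = c("unpaired", "paired"),
                                  exact_n_max = 15) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (length(a) != length(b)) abort("paired mode requires equal lengths",
                                      class = "pw_stats_error")
    d <- a - b
    n_eff <- sum(d != 0)
    if (n_eff == 0) abort("all paired differences are zero: statistic undefined",
                          class = "pw_stats_error")
    ties <- any(duplicated(abs(d[d != 0])))
    ht <- suppressWarnings(
      wilcox.test(a, b, paired = TRUE, correct = TRUE,
                  exact = n_eff <= exact_n_max && !ties))
    n <- n_eff
  } else {
    ties <- any(duplicated(c(a, b)))
    ht <- suppressWarnings(
      wilcox.test(a, b, paired = FALSE, correct = TRUE,
                  exact = max(length(a), length(b)) <= exact_n_max && !ties))
    n <- length(a) + length(b)
  }
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = ht$method, n = n)
}

r_squared <- function(data, response, terms) {
  fml <- if (length(terms) == 0) {
    stats::as.formula(paste(response, "~ 1"))
  } else {
    stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  }
  fit <- lm(fml, data = data)
  list(r2 = summary(fit)$r.squared, fit = fit,
       rank_ok = fit$rank == length(coef(fit)) - sum(is.na(coef(fit))) &&
         !any(is.na(coef(fit))))
}

#' Stepwise regression with an R-squared criterion
#'
#' Forward-add / backward-remove selection over main effects and pairwise
#' interactions: a term enters if it improves R-squared by at least
#' `delta_add` (0.1) and a term leaves if its contribution (R-squared drop on
#' removal) is below `delta_remove` (0.05), iterated to a fixed point. Ties
#' break by largest R-squared gain, then lowest candidate index. With
#' `hierarchy = TRUE` an interaction is eligible only once both its main
#' effects are in the model.
#'
#' @param data complete-case data frame.
#' @param response response column name (e.g. the augmentation index).
#' @param predictors candidate main-effect column names; defaults to all
#'   columns except the response.
#' @param delta_add,delta_remove R-squared entry/removal thresholds.
#' @param interactions include pairwise interactions as candidates.
#' @param hierarchy require both main effects before an interaction.
#' @param max_steps safety cap on add/remove sweeps.
#' @return A `stepwise_model`: selected `terms`, `coefficients`, `r2`,
#'   `adj_r2`, the fitted `lm`, and a selection `trace`. Supports `tidy()`
#'   and `glance()`.
#' @export
stepwise_regression <- function(data, response, predictors = setdiff(names(data), response),
                                delta_add = 0.1, delta_remove = 0.05,
                                interactions = TRUE, hierarchy = TRUE,
                                max_steps = 50) {
  stopifnot(response %in% names(data))
  if (anyNA(data[c(response, predictors)])) {
    abort("complete cases required", class = "pw_stats_error")
  }
  if (nrow(data) <= length(predictors)) {
    abort("need more observations than candidate main effects", class = "pw_stats_error")
  }
  mains <- predictors
  inters <- if (interactions && length(mains) > 1) {
    cmb <- utils::combn(mains, 2)
    paste(cmb[1, ], cmb[2, ], sep = ":")
  } else character(0)
  candidates <- c(mains, inters)

  selected <- character(0)
  trace <- list()
  r2_cur <- 0
  for (step_i in seq_len(max_steps)) {
    changed <- FALSE
    # ---- add phase
    elig <- setdiff(candidates, selected)
    if (hierarchy) {
      elig <- elig[vapply(elig, function(tm) {
        if (!grepl(":", tm)) return(TRUE)
        all(strsplit(tm, ":")[[1]] %in% selected)
      }, TRUE)]
    }
    if (length(elig) > 0) {
      gains <- vapply(elig, function(tm) {
        rs <- r_squared(data, response, c(selected, tm))
        if (!rs$rank_ok) return(NA_real_)  # rank-deficient: reject
        rs$r2 - r2_cur
      }, 1.0)
      rejected <- names(gains)[is.na(gains)]
      for (tm in rejected) {
        trace[[length(trace) + 1]] <- tibble(action = "reject_rank", term = tm,
                                             r2 = r2_cur)
      }
      gains_ok <- gains[!is.na(gains)]
      if (length(gains_ok) > 0 && max(gains_ok) >= delta_add) {
        # tie-break: largest gain, then lowest candidate index
        best_gain <- max(gains_ok)
        cands <- names(gains_ok)[gains_ok >= best_gain - 1e-12]
        tm <- cands[which.min(match(cands, candidates))]
        selected <- c(selected, tm)
        r2_cur <- r_squared(data, response, selected)$r2
        trace[[length(trace) + 1]] <- tibble(action = "add", term = tm, r2 = r2_cur)
        changed <- TRUE
      }
    }
    # ---- remove phase (iterate until stable)
    repeat {
      removable <- selected
      if (hierarchy) {
        needed <- unique(unlist(lapply(selected[grepl(":", selected)],
                                       function(tm) strsplit(tm, ":")[[1]])))
        removable <- setdiff(removable, needed)
      }
      if (length(removable) == 0) break
      contrib <- vapply(removable, function(tm) {
        r2_cur - r_squared(data, response, setdiff(selected, tm))$r2
      }, 1.0)
      if (min(contrib) < delta_remove) {
        worst <- min(contrib)
        cands <- names(contrib)[contrib <= worst + 1e-12]
        tm <- cands[which.min(match(cands, candidates))]
        selected <- setdiff(selected, tm)
        r2_cur <- r_squared(data, response, selected)$r2
        trace[[length(trace) + 1]] <- tibble(action = "remove", term = tm, r2 = r2_cur)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  rs <- r_squared(data, response, selected)
  smr <- summary(rs$fit)
  structure(list(terms = selected,
                 coefficients = coef(rs$fit),
                 r2 = smr$r.squared, adj_r2 = smr$adj.r.squared,
                 fit = rs$fit, response = response,
                 trace = if (length(trace)) dplyr::bind_rows(trace) else
                   tibble(action = character(), term = character(), r2 = numeric())),
            class = "stepwise_model")
}

#' Stepwise regression of augmentation index on model parameters
#'
#' Builds the canonical candidate set {k1, k3, 1/k1, 1/k3, S_R, S_C, CO, tau,
#' SV} from a cohort table and runs [stepwise_regression()] against the
#' augmentation index.
#'
#' @param cohort data frame with columns `k1`, `k3`, `co`, `tau`, `s_r`,
#'   `s_c`, `sv` (ml) and the response.
#' @param response response column (default `"AI"`).
#' @inheritParams stepwise_regression
#' @return A `stepwise_model`.
#' @export
stepwise_ai_regression <- function(cohort, response = "AI",
                                   delta_add = 0.1, delta_remove = 0.05,
                                   interactions = TRUE, hierarchy = TRUE) {
  need <- c("k1", "k3", "co", "tau", "s_r", "s_c", "sv", response)
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) {
    abort(paste0("cohort lacks column(s): ", paste(miss, collapse = ", ")),
          class = "pw_stats_error")
  }
  dat <- tibble(
    k1 = cohort$k1, k3 = cohort$k3,
    inv_k1 = 1 / cohort$k1, inv_k3 = 1 / cohort$k3,
    s_r = cohort$s_r, s_c = cohort$s_c,
    co = cohort$co, tau = cohort$tau, sv = cohort$sv
  )
  dat[[response]] <- cohort[[response]]
  stepwise_regression(dat, response,
                      predictors = c("k1", "k3", "inv_k1", "inv_k3",
                                     "s_r", "s_c", "co", "tau", "sv"),
                      delta_add = delta_add, delta_remove = delta_remove,
                      interactions = interactions, hierarchy = hierarchy)
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("<stepwise_model> %s ~ %s (R2=%.3f, adj R2=%.3f)\n",
              x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$r2, x$adj_r2))
  invisible(x)
}

#' @rdname stepwise_regression
#' @param x a `stepwise_model`.
#' @param ... unused.
#' @export
tidy.stepwise_model <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname stepwise_regression
#' @export
glance.stepwise_model <- function(x, ...) {
  tibble(r2 = x$r2, adj_r2 = x$adj_r2, n_terms = length(x$terms))
}
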