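#' Read a subjects-by-variables table and its role manifest
#'
#' The table is a CSV with a header row of unique variable names and one
#' row per subject; empty cells are missing. The manifest is a JSON object
#' `{"dependent": [...], "independent": [...]}` naming which columns play
#' which role.
#'
#' @param table_path path to the CSV table.
#' @param manifest_path path to the JSON manifest.
#' @return a list with elements `table` (data frame) and `manifest`
#'   (list with `dependent` and `independent` character vectors).
#' @export
read_study <- function(table_path, manifest_path) {
  table <- utils::read.csv(table_path, check.names = FALSE)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  validate_manifest(table, manifest)
  list(table = table, manifest = manifest)
}

validate_manifest <- function(table, manifest) {
  if (is.null(manifest$dependent) || is.null(manifest$independent)) {
    stop("manifest must list 'dependent' and 'independent' variables",
         call. = FALSE)
  }
  if (anyDuplicated(names(table))) {
    stop("table column names must be unique", call. = FALSE)
  }
  both <- intersect(manifest$dependent, manifest$independent)
  if (length(both)) {
    stop("variables cannot be both dependent and independent: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(c(manifest$dependent, manifest$independent), names(table))
  if (length(absent)) {
    stop("manifest names absent from table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  invisible(manifest)
}

#' Number of coefficient-level tests a study design registers
#'
#' One linear model per dependent variable, with every independent
#' variable as a regressor, yields `dependents x independents`
#' coefficient tests in total.
#'
#' @param manifest a role manifest (list with `dependent` and
#'   `independent` character vectors).
#' @return the total test count.
#' @examples
#' n_planned_tests(list(dependent = c("a", "b"), independent = c("x", "y")))
#' @export
n_planned_tests <- function(manifest) {
  length(manifest$dependent) * length(manifest$independent)
}

#' Standardise every column to mean 0, standard deviation 1
#'
#' Moments are computed on the non-missing entries of each column using
#' the sample (n - 1) standard deviation; missing cells stay missing.
#' Standardisation happens before any listwise deletion, so all models
#' see the same scaling of a given variable.
#'
#' @param table a data frame of numeric columns (missing values allowed).
#' @return the standardised data frame.
#' @export
standardize_columns <- function(table) {
  for (nm in names(table)) {
    x <- table[[nm]]
    if (!is.numeric(x)) {
      stop("column '", nm, "' is not numeric", call. = FALSE)
    }
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      stop("column '", nm, "' is constant (or all missing); ",
           "cannot standardise", call. = FALSE)
    }
    table[[nm]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Fit one ordinary-least-squares model and extract coefficient p-values
#'
#' Regresses the dependent variable on all independent variables jointly
#' (with intercept), after listwise deletion of rows missing any involved
#' variable. Each regressor's two-tailed p-value comes from the t-test on
#' its coefficient with residual degrees of freedom, as reported by
#' [stats::lm()].
#'
#' @param table a (standardised) data frame.
#' @param dv name of the dependent variable.
#' @param ivs character vector of independent-variable names.
#' @return a list with `dependent_name`, `p_values` (named numeric vector
#'   over `ivs`) and `n_used` (rows remaining after deletion).
#' @export
fit_model_pvalues <- function(table, dv, ivs) {
  cols <- table[, c(dv, ivs), drop = FALSE]
  keep <- stats::complete.cases(cols)
  n_used <- sum(keep)
  if (n_used < length(ivs) + 2L) {
    stop("model for '", dv, "': only ", n_used,
         " complete rows for ", length(ivs), " regressors", call. = FALSE)
  }
  d <- cols[keep, , drop = FALSE]
  names(d) <- c(".dv", paste0(".x", seq_along(ivs)))
  fit <- stats::lm(.dv ~ ., data = d)
  if (anyNA(stats::coef(fit))) {
    stop("model for '", dv, "': design matrix is rank deficient",
         call. = FALSE)
  }
  coefs <- summary(fit)$coefficients
  p <- coefs[-1L, "Pr(>|t|)"]
  names(p) <- ivs
  list(dependent_name = dv, p_values = p, n_used = n_used)
}

#' Fit every model of a study design
#'
#' @param table a data frame (standardised internally unless
#'   `standardize = FALSE`).
#' @param manifest a role manifest.
#' @param standardize standardise columns first (default `TRUE`).
#' @return a named list of [fit_model_pvalues()] results, one per
#'   dependent variable.
#' @export
fit_all_models <- function(table, manifest, standardize = TRUE) {
  validate_manifest(table, manifest)
  used <- unique(c(manifest$dependent, manifest$independent))
  table <- table[, used, drop = FALSE]
  if (standardize) table <- standardize_columns(table)
  results <- lapply(manifest$dependent, function(dv)
    fit_model_pvalues(table, dv, manifest$independent))
  names(results) <- manifest$dependent
  results
}

#' Simultaneous baseline over the pooled test family
#'
#' Pools every coefficient p-value from every model into one family of
#' `dependents x independents` tests and applies a single simultaneous
#' correction. This is the reference against which sequential schemes are
#' compared: it is invariant to the order of the dependent variables.
#'
#' @param model_results output of [fit_all_models()].
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @param alpha familywise level / FDR target.
#' @return a data frame of findings with columns `dependent`,
#'   `independent`, `p_value` (zero rows if nothing is significant).
#' @export
baseline_simultaneous <- function(model_results,
                                  method = c("bonferroni", "bh_fdr"),
                                  alpha = 0.05) {
  method <- match.arg(method)
  pool <- do.call(rbind, lapply(model_results, function(r)
    data.frame(dependent = r$dependent_name, independent = names(r$p_values),
               p_value = unname(r$p_values))))
  rownames(pool) <- NULL
  decisions <- switch(method,
    bonferroni = bonferroni_reject(pool$p_value, alpha),
    bh_fdr     = bh_fdr_reject(pool$p_value, alpha)
  )
  pool[decisions$rejected, , drop = FALSE]
}

#' Informed ordering of dependent variables
#'
#' Emulates analysts who preferentially test promising hypotheses first:
#' while both pools are non-empty, each position in the sequence is drawn
#' from the baseline-positive or baseline-negative pool with probability
#' one half each (then uniformly within the chosen pool); once a pool is
#' empty, a uniform shuffle of the survivors fills the tail.
#'
#' @param positive_dependents,negative_dependents disjoint character
#'   vectors that together cover all dependent variables.
#' @return a permutation of `c(positive_dependents, negative_dependents)`.
#' @export
informed_order <- function(positive_dependents, negative_dependents) {
  pos <- sample(positive_dependents)
  neg <- sample(negative_dependents)
  out <- character(length(pos) + length(neg))
  ip <- 1L; im <- 1L
  for (i in seq_along(out)) {
    if (ip > length(pos)) {
      out[i] <- neg[im]; im <- im + 1L
    } else if (im > length(neg)) {
      out[i] <- pos[ip]; ip <- ip + 1L
    } else if (stats::runif(1) < 0.5) {
      out[i] <- pos[ip]; ip <- ip + 1L
    } else {
      out[i] <- neg[im]; im <- im + 1L
    }
  }
  out
}

#' Hybrid sequential-plus-simultaneous mass-univariate pipeline
#'
#' Walks the dependent variables in a (random or informed) order. At
#' sequential step `i` the chosen sequential policy supplies the level
#' `alpha_i`; the i-th model's coefficient p-values are then corrected
#' simultaneously (within-model) at that level. A model counts as a
#' rejection for the sequential state (relevant to alpha-investing's
#' wealth) when it yields at least one within-model finding. Two summary
#' statistics are tracked per permutation: `findings`, the number of
#' significant coefficient tests over all models, and `positive_studies`,
#' the number of models with at least one finding — a proxy for how many
#' publications would claim a positive result.
#'
#' @param table a data frame (see [read_study()]).
#' @param manifest a role manifest.
#' @param sequential_policy a sequential [threshold_policy()].
#' @param order_scheme `"uniform"` (orders are uniform shuffles) or
#'   `"informed"` (baseline positives are weighted early; see
#'   [informed_order()]). Baseline positives are the dependents with at
#'   least one finding under either pooled simultaneous baseline.
#' @param n_permutations number of order permutations (default 100).
#' @param within_model_method simultaneous correction applied within each
#'   model: `"bh_fdr"` (default) or `"bonferroni"`.
#' @param alpha level of the pooled simultaneous baselines.
#' @param seed integer seed making the permutation set reproducible.
#' @return an object of class `pipeline_summary`: a list with
#'   `per_permutation` (data frame: `permutation`, `policy`, `findings`,
#'   `positive_studies`), `summary` (mean/sd/min/max of both counts),
#'   `baseline` (finding counts of the pooled baselines), and the run
#'   parameters.
#' @export
run_pipeline <- function(table, manifest, sequential_policy,
                         order_scheme = c("uniform", "informed"),
                         n_permutations = 100,
                         within_model_method = c("bh_fdr", "bonferroni"),
                         alpha = 0.05, seed = 42L) {
  order_scheme <- match.arg(order_scheme)
  within_model_method <- match.arg(within_model_method)
  if (!inherits(sequential_policy, "threshold_policy") ||
      !is_sequential_policy(sequential_policy)) {
    stop("'sequential_policy' must be a sequential threshold_policy",
         call. = FALSE)
  }
  models <- fit_all_models(table, manifest)
  base_bonf <- baseline_simultaneous(models, "bonferroni", alpha)
  base_bh <- baseline_simultaneous(models, "bh_fdr", alpha)
  positives <- union(base_bonf$dependent, base_bh$dependent)
  negatives <- setdiff(manifest$dependent, positives)

  per_perm <- data.frame(permutation = seq_len(n_permutations),
                         policy = sequential_policy$name,
                         findings = NA_integer_,
                         positive_studies = NA_integer_)
  set.seed(seed)
  for (perm in seq_len(n_permutations)) {
    order_i <- switch(order_scheme,
      uniform = sample(manifest$dependent),
      informed = informed_order(positives, negatives)
    )
    walk <- walk_models_sequentially(models[order_i], sequential_policy,
                                     within_model_method)
    per_perm$findings[perm] <- walk$findings
    per_perm$positive_studies[perm] <- walk$positive_studies
  }
  summarise1 <- function(x) c(mean = mean(x), sd = stats::sd(x),
                              min = min(x), max = max(x))
  structure(list(
    per_permutation = per_perm,
    summary = list(findings = summarise1(per_perm$findings),
                   positive_studies = summarise1(per_perm$positive_studies)),
    baseline = c(bonferroni = nrow(base_bonf), bh_fdr = nrow(base_bh)),
    baseline_positive_dependents = positives,
    n_permutations = n_permutations,
    policy = sequential_policy, order_scheme = order_scheme,
    within_model_method = within_model_method, alpha = alpha, seed = seed
  ), class = "pipeline_summary")
}

# Walk ordered models: derive alpha_i sequentially, correct within each
# model simultaneously at alpha_i, and feed "any finding" back into the
# sequential state.
walk_models_sequentially <- function(ordered_models, policy,
                                     within_model_method) {
  findings <- 0L
  positive_studies <- 0L
  p_par <- policy$parameters
  w <- if (policy$name == "alpha_investing") p_par$w0 else NA_real_
  remaining <- if (policy$name == "alpha_spending") p_par$alpha0 else NA_real_
  for (i in seq_along(ordered_models)) {
    alpha_i <- switch(policy$name,
      uncorrected    = p_par$alpha,
      alpha_debt     = p_par$alpha1 / i,
      alpha_spending = {
        a <- p_par$s * remaining
        remaining <- remaining - a
        a
      },
      alpha_investing = p_par$s * w
    )
    if (alpha_i < .Machine$double.xmin) alpha_i <- 0
    # investing wealth can grow past 1 after repeated payouts; a level of
    # 1 or more rejects everything, so cap just below 1 for the
    # within-model correction
    if (alpha_i >= 1) alpha_i <- 1 - .Machine$double.eps
    n_found <- if (alpha_i > 0) {
      pv <- ordered_models[[i]]$p_values
      switch(within_model_method,
        bh_fdr     = sum(bh_fdr_reject(pv, alpha_i)$rejected),
        bonferroni = sum(bonferroni_reject(pv, alpha_i)$rejected))
    } else 0L
    findings <- findings + n_found
    positive_studies <- positive_studies + (n_found > 0L)
    if (policy$name == "alpha_investing") {
      w <- if (n_found > 0L) w + p_par$omega else w - alpha_i / (1 - alpha_i)
    }
  }
  list(findings = findings, positive_studies = positive_studies)
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("<pipeline_summary> policy:", x$policy$name,
      "| order:", x$order_scheme,
      "| within-model:", x$within_model_method, "\n")
  cat(sprintf("  findings:          mean %.2f (sd %.2f, min %d, max %d)\n",
              x$summary$findings["mean"], x$summary$findings["sd"],
              as.integer(x$summary$findings["min"]),
              as.integer(x$summary$findings["max"])))
  cat(sprintf("  positive studies:  mean %.2f (sd %.2f, min %d, max %d)\n",
              x$summary$positive_studies["mean"],
              x$summary$positive_studies["sd"],
              as.integer(x$summary$positive_studies["min"]),
              as.integer(x$summary$positive_studies["max"])))
  cat("  pooled baselines (findings): bonferroni", x$baseline["bonferroni"],
      "| bh_fdr", x$baseline["bh_fdr"], "\n")
  invisible(x)
}

#' Serialise a pipeline summary
#'
#' Writes the aggregate summary as JSON and, optionally, the
#' per-permutation counts as CSV.
#'
#' @param x a `pipeline_summary`.
#' @param json_path output path for the JSON summary.
#' @param csv_path optional output path for the per-permutation CSV.
#' @return `json_path`, invisibly.
#' @export
write_pipeline_summary <- function(x, json_path, csv_path = NULL) {
  stopifnot(inherits(x, "pipeline_summary"))
  out <- list(policy = x$policy$name,
              parameters = x$policy$parameters,
              order_scheme = x$order_scheme,
              within_model_method = x$within_model_method,
              alpha = x$alpha, seed = x$seed,
              n_permutations = x$n_permutations,
              findings = as.list(x$summary$findings),
              positive_studies = as.list(x$summary$positive_studies),
              baseline_findings = as.list(x$baseline))
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    utils::write.csv(x$per_permutation, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
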