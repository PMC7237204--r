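#' Specify a synthetic study table
#'
#' Describes a subjects-by-variables table with the shape of a large
#' shared neuroimaging-and-behaviour study: many continuous outcome
#' (dependent) variables, a block of predictor (independent) variables,
#' optional planted linear effects, and completely-at-random missingness.
#' The defaults mirror a 1000-subject study with 68 predictors and 182
#' outcomes. All generated data are synthetic.
#'
#' @param n_subjects rows of the table (default 1000).
#' @param n_independent number of predictor columns (default 68).
#' @param n_dependent number of outcome columns (default 182).
#' @param planted a data frame (or NULL) with columns `dependent`,
#'   `independent` (1-based indices) and `beta` (standardised effect
#'   size): outcome `dependent` receives `beta` times predictor
#'   `independent` on top of unit Gaussian noise.
#' @param missing_rate probability that any one cell is masked missing,
#'   in \[0, 0.5).
#' @param seed integer seed.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_subjects = 1000, n_independent = 68,
                         n_dependent = 182, planted = NULL,
                         missing_rate = 0, seed = 42L) {
  check_index(n_subjects, "n_subjects")
  check_index(n_independent, "n_independent")
  check_index(n_dependent, "n_dependent")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 0.5) {
    stop("'missing_rate' must lie in [0, 0.5)", call. = FALSE)
  }
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("dependent", "independent", "beta") %in% names(planted)))
    if (any(planted$dependent < 1 | planted$dependent > n_dependent) ||
        any(planted$independent < 1 | planted$independent > n_independent)) {
      stop("planted effect indices out of range", call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_independent = as.integer(n_independent),
                 n_dependent = as.integer(n_dependent),
                 planted = planted, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic study from a specification
#'
#' Predictors are drawn iid standard Gaussian; each outcome is the sum of
#' its planted effects (`beta` times the named predictor) plus unit
#' Gaussian noise; cells are then masked missing independently at
#' `missing_rate`. Column names are `iv_1 ... iv_K` and `dv_1 ... dv_J`.
#' The same spec (including seed) always regenerates the same table.
#'
#' @param spec a [fixture_spec()].
#' @return a list with `table` (data frame), `manifest` (role lists) and
#'   `ground_truth` (data frame of planted `dependent`/`independent`
#'   column-name pairs with their `beta`; zero rows if none planted).
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  iv_names <- paste0("iv_", seq_len(spec$n_independent))
  dv_names <- paste0("dv_", seq_len(spec$n_dependent))
  ivs <- matrix(stats::rnorm(n * spec$n_independent), nrow = n,
                dimnames = list(NULL, iv_names))
  dvs <- matrix(stats::rnorm(n * spec$n_dependent), nrow = n,
                dimnames = list(NULL, dv_names))
  if (!is.null(spec$planted)) {
    for (r in seq_len(nrow(spec$planted))) {
      j <- spec$planted$dependent[r]
      k <- spec$planted$independent[r]
      dvs[, j] <- dvs[, j] + spec$planted$beta[r] * ivs[, k]
    }
  }
  table <- cbind(as.data.frame(dvs), as.data.frame(ivs))
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * ncol(table)) < spec$missing_rate,
                   nrow = n)
    table[mask] <- NA_real_
  }
  ground_truth <- if (is.null(spec$planted)) {
    data.frame(dependent = character(0), independent = character(0),
               beta = numeric(0))
  } else {
    data.frame(dependent = dv_names[spec$planted$dependent],
               independent = iv_names[spec$planted$independent],
               beta = spec$planted$beta)
  }
  list(table = table,
       manifest = list(dependent = dv_names, independent = iv_names),
       ground_truth = ground_truth)
}

#' Write a synthetic study to disk
#'
#' Emits the CSV table and JSON manifest in exactly the formats
#' [read_study()] consumes, plus the ground-truth pairs as CSV.
#'
#' @param study output of [generate_study()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"study"`).
#' @return the paths, invisibly.
#' @export
write_study <- function(study, dir, prefix = "study") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  table_path <- file.path(dir, paste0(prefix, "_table.csv"))
  manifest_path <- file.path(dir, paste0(prefix, "_manifest.json"))
  truth_path <- file.path(dir, paste0(prefix, "_ground_truth.csv"))
  utils::write.csv(study$table, table_path, row.names = FALSE, na = "")
  jsonlite::write_json(study$manifest, manifest_path)
  utils::write.csv(study$ground_truth, truth_path, row.names = FALSE)
  invisible(list(table = table_path, manifest = manifest_path,
                 ground_truth = truth_path))
}
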