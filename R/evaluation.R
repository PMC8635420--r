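#' Sample negative drug-protein pairs
#'
#' Draws `round(ratio * nrow(positives))` pairs uniformly without replacement
#' from `(drugs x proteins) \ known_positives`.  If the requested count
#' exceeds the pool, the whole pool is returned with a warning.  The usual
#' protocol labels known interactions positive and samples ten times as many
#' unlabeled pairs as negatives (`ratio = 10`); `ratio = 1` gives the
#' balanced setting.  Deterministic per seed.
#'
#' @param positives Tibble with columns `drug`, `protein`: the positives the
#'   count is based on.
#' @param drugs,proteins Character vectors defining the candidate pair
#'   universe.
#' @param ratio Negatives per positive (> 0).
#' @param seed Integer seed.
#' @param exclude Tibble of pairs that must never be sampled (defaults to
#'   `positives`; pass the full known-positive set to forbid labeling any
#'   known interaction as negative).
#' @return Tibble with columns `drug`, `protein`, `label` (all 0).
#' @export
sample_negatives <- function(positives, drugs, proteins, ratio = 10, seed = 1,
                             exclude = positives) {
  stopifnot(ratio > 0)
  drugs <- unique(drugs); proteins <- unique(proteins)
  nd <- length(drugs); np <- length(proteins)
  excl_keys <- unique(paste(exclude$drug, exclude$protein, sep = "\t"))
  pool_size <- nd * np - sum(excl_keys %in%
                               paste(rep(drugs, times = np),
                                     rep(proteins, each = nd), sep = "\t"))
  if (pool_size <= 0) {
    stop("sample_negatives(): empty negative pool", call. = FALSE)
  }
  want <- round(ratio * nrow(positives))
  if (want > pool_size) {
    warning("sample_negatives(): pool exhausted; returning all ", pool_size,
            " available negatives instead of ", want, call. = FALSE)
    want <- pool_size
  }
  picked <- character(0)
  local_seed(seed, {
    # rejection sampling over the flat pair index, with an exhaustive
    # fallback when the free pool gets tight
    remaining <- want
    seen <- character(0)
    for (round in 1:64) {
      if (remaining == 0) break
      idx <- sample.int(nd * np, min(nd * np, remaining * 2), replace = TRUE)
      cand <- paste(drugs[(idx - 1) %% nd + 1],
                    proteins[(idx - 1) %/% nd + 1], sep = "\t")
      cand <- cand[!(cand %in% excl_keys) & !(cand %in% seen)]
      cand <- cand[!duplicated(cand)]
      take <- utils::head(cand, remaining)
      seen <- c(seen, take)
      remaining <- want - length(seen)
    }
    if (remaining > 0) {
      all_keys <- paste(rep(drugs, times = np), rep(proteins, each = nd),
                        sep = "\t")
      free <- setdiff(all_keys, c(excl_keys, seen))
      seen <- c(seen, free[sample.int(length(free), remaining)])
    }
    picked <- seen
  })
  parts <- strsplit(picked, "\t", fixed = TRUE)
  tibble::tibble(drug = purrr::map_chr(parts, 1),
                 protein = purrr::map_chr(parts, 2),
                 label = 0)
}

#' Build a cross-validation fold plan
#'
#' Three scenarios:
#' * `"warm"` (drug repurposing): positives are shuffled and split into k
#'   parts; train and test share drugs and proteins.
#' * `"cold_drug"`: drugs are partitioned into k groups; every positive of a
#'   test-group drug is test data, so test drugs never appear in training
#'   pairs.
#' * `"cold_protein"`: symmetric for proteins (new-target discovery).
#'
#' Negatives are sampled per fold and per side after splitting, at
#' `ratio` negatives per positive, always excluding the *full* known-positive
#' set, and — in cold scenarios — drawn only over the side's own
#' drugs/proteins so entity disjointness also holds for negatives.
#'
#' @param positives Tibble with columns `drug`, `protein`.
#' @param scenario `"warm"`, `"cold_drug"`, or `"cold_protein"`.
#' @param k Number of folds (>= 2).
#' @param ratio Negatives per positive (10 = the unbalanced protocol,
#'   1 = balanced).
#' @param seed Integer seed.
#' @param drugs,proteins Optional pair universe (defaults to the entities of
#'   `positives`).
#' @return An object of class `fold_plan`: list with `scenario`, `k`,
#'   `ratio`, `seed` and `folds`, each fold a list of labeled `train` and
#'   `test` tibbles (`drug`, `protein`, `label`).
#' @export
make_folds <- function(positives, scenario = c("warm", "cold_drug",
                                               "cold_protein"),
                       k = 10, ratio = 10, seed = 1,
                       drugs = NULL, proteins = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(k >= 2)
  positives <- dplyr::distinct(tibble::as_tibble(positives)[, c("drug", "protein")])
  positives$label <- 1
  drugs <- unique(drugs %||% positives$drug)
  proteins <- unique(proteins %||% positives$protein)
  n <- nrow(positives)
  assign_groups <- function(ids, what) {
    if (length(ids) < k) {
      stop("make_folds(): ", length(ids), " distinct ", what,
           " cannot be split into ", k, " folds", call. = FALSE)
    }
    g <- NULL
    local_seed(seed_from(seed, 11L), {
      g <- sample(rep(seq_len(k), length.out = length(ids)))
    })
    stats::setNames(g, ids)
  }
  fold_of <- switch(scenario,
    warm = {
      f <- NULL
      local_seed(seed_from(seed, 11L),
                 f <- sample(rep(seq_len(k), length.out = n)))
      f
    },
    cold_drug = unname(assign_groups(sort(unique(positives$drug)),
                                     "drugs")[positives$drug]),
    cold_protein = unname(assign_groups(sort(unique(positives$protein)),
                                        "proteins")[positives$protein]))
  folds <- purrr::map(seq_len(k), function(i) {
    test_pos <- positives[fold_of == i, ]
    train_pos <- positives[fold_of != i, ]
    if (scenario == "warm") {
      train_d <- drugs; train_p <- proteins
      test_d <- drugs; test_p <- proteins
    } else if (scenario == "cold_drug") {
      test_d <- unique(test_pos$drug); train_d <- setdiff(drugs, test_d)
      train_p <- test_p <- proteins
    } else {
      test_p <- unique(test_pos$protein); train_p <- setdiff(proteins, test_p)
      train_d <- test_d <- drugs
    }
    train_neg <- sample_negatives(train_pos, train_d, train_p, ratio,
                                  seed = seed_from(seed, 100L * i + 1L),
                                  exclude = positives)
    test_neg <- sample_negatives(test_pos, test_d, test_p, ratio,
                                 seed = seed_from(seed, 100L * i + 2L),
                                 exclude = positives)
    list(train = dplyr::bind_rows(train_pos, train_neg),
         test = dplyr::bind_rows(test_pos, test_neg))
  })
  structure(list(scenario = scenario, k = as.integer(k), ratio = ratio,
                 seed = as.integer(seed), folds = folds),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> scenario:", x$scenario, "| k =", x$k,
      "| 1:", x$ratio, "positives:negatives | seed", x$seed, "\n")
  invisible(x)
}

#' Export / import a fold plan as JSON
#'
#' @param plan A `fold_plan` object.
#' @param path File path.
#' @return `path` (writer); a `fold_plan` (reader).
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(
    list(scenario = plan$scenario, k = plan$k, ratio = plan$ratio,
         seed = plan$seed,
         folds = purrr::map(plan$folds, ~ list(train = .x$train, test = .x$test))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(scenario = obj$scenario, k = as.integer(obj$k),
                 ratio = obj$ratio, seed = as.integer(obj$seed),
                 folds = purrr::map(seq_len(obj$k), function(i) {
                   list(train = tibble::as_tibble(obj$folds$train[[i]]),
                        test = tibble::as_tibble(obj$folds$test[[i]]))
                 })),
            class = "fold_plan")
}

#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a random positive is
#' scored above a random negative, with ties counted 1/2 (equivalent to the
#' normalized Mann-Whitney U computed from mid-ranks).
#'
#' @param labels Binary vector (both classes required).
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("auroc(): both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation of precision times recall increment over descending
#' score thresholds, with tied scores processed as a single block (no linear
#' interpolation between operating points).  This is the main metric under
#' 1:10 class imbalance, where ROC curves are insensitive to the class
#' distribution.
#'
#' @inheritParams auroc
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(labels, scores) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("aupr(): no positive labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # block boundaries: last index of each run of tied scores
  block_end <- cumsum(rle(sc)$lengths)
  tp <- cumsum(lab)[block_end]
  pred_pos <- block_end
  precision <- tp / pred_pos
  recall <- tp / n_pos
  sum(precision * diff(c(0, recall)))
}

#' Cross-validated evaluation of a DTI pipeline
#'
#' Runs [dti_fit()] / [dti_predict()] on each fold of a [make_folds()] plan
#' (the KGE is retrained per fold on the supporting KG plus that fold's
#' training positives, so no test interaction ever reaches embedding
#' training) and scores each test side with [auroc()] and [aupr()].
#' Deterministic per seed.
#'
#' @param positives Tibble of positive pairs (`drug`, `protein`).
#' @param kg A `kg` object (the supporting KG; any DTI triples it carries
#'   are ignored during fitting in favor of the fold's own training
#'   positives).
#' @param config A [dti_config()] list.
#' @param scenario,k,ratio Passed to [make_folds()].
#' @param folds Optional integer vector restricting which folds to run
#'   (default: all k).
#' @param scorer Optional override `function(fold, kg, config) -> numeric`
#'   returning one score per test row, used in place of the fitted pipeline
#'   (plumbing hook for oracle/stub scorers in tests).
#' @return An object of class `dti_eval`: list with `metrics` (tibble:
#'   `fold`, `scenario`, `auroc`, `aupr`) and `summary` (tibble of box-plot
#'   statistics: median, lower/upper quartile by linear interpolation,
#'   minimum, maximum per metric).
#' @export
cross_validate <- function(positives, kg, config = dti_config(),
                           scenario = "warm", k = 10, ratio = 10,
                           folds = NULL, scorer = NULL) {
  plan <- make_folds(positives, scenario, k = k, ratio = ratio,
                     seed = config$seed)
  run <- folds %||% seq_len(plan$k)
  metrics <- purrr::map_dfr(run, function(i) {
    fold <- plan$folds[[i]]
    scores <- tryCatch({
      if (is.null(scorer)) {
        fit <- dti_fit(fold$train, kg, config)
        dti_predict(fit, fold$test)$probability
      } else {
        scorer(fold, kg, config)
      }
    }, error = function(e) {
      stop("cross_validate(): fold ", i, ": ", conditionMessage(e),
           call. = FALSE)
    })
    roc <- auroc(fold$test$label, scores)
    pr <- aupr(fold$test$label, scores)
    tibble::tibble(fold = i, scenario = plan$scenario,
                   auroc = roc, aupr = pr)
  })
  structure(list(metrics = metrics, summary = eval_summary(metrics),
                 scenario = plan$scenario, seed = config$seed),
            class = "dti_eval")
}

# box-plot statistics per metric (quartiles by linear interpolation, type 7)
eval_summary <- function(metrics) {
  metrics |>
    tidyr::pivot_longer(c("auroc", "aupr"), names_to = "metric") |>
    dplyr::group_by(.data$scenario, .data$metric) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      q1 = unname(stats::quantile(.data$value, 0.25, type = 7)),
      q3 = unname(stats::quantile(.data$value, 0.75, type = 7)),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop")
}

#' @export
print.dti_eval <- function(x, ...) {
  cat("<dti_eval> scenario:", x$scenario, "|", nrow(x$metrics), "fold(s)\n")
  print(x$summary)
  invisible(x)
}

#' Tidy per-fold metrics of a cross-validation run
#' @param x A `dti_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @export
tidy.dti_eval <- function(x, ...) x$metrics

#' One-row summary of a cross-validation run
#' @param x A `dti_eval` object.
#' @param ... Unused.
#' @return One-row tibble with median AUROC/AUPR.
#' @export
glance.dti_eval <- function(x, ...) {
  tibble::tibble(scenario = x$scenario,
                 n_folds = nrow(x$metrics),
                 median_auroc = stats::median(x$metrics$auroc),
                 median_aupr = stats::median(x$metrics$aupr))
}

#' Box plot of per-fold AUROC/AUPR
#' @param object A `dti_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dti_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, c("auroc", "aupr"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = paste("scenario:", object$scenario)) +
    ggplot2::theme_minimal()
}

#' Write per-fold metrics (and a JSON summary) to disk
#'
#' The TSV is written with full precision so identical runs produce
#' byte-identical files.
#'
#' @param x A `dti_eval` object.
#' @param path TSV output path.
#' @param summary_path Optional JSON path for the box-plot summary.
#' @return `path`, invisibly.
#' @export
write_eval <- function(x, path, summary_path = NULL) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines("fold\tscenario\tauroc\taupr", con)
  writeLines(sprintf("%d\t%s\t%.17g\t%.17g", x$metrics$fold,
                     x$metrics$scenario, x$metrics$auroc, x$metrics$aupr), con)
  if (!is.null(summary_path)) {
    jsonlite::write_json(x$summary, summary_path, digits = NA)
  }
  invisible(path)
}
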