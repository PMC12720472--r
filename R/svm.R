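# Per-parameter two-group classification accuracy: RBF-SVM scored by
# bootstrap resampling plus leave-one-out cross-validation.

# One LOOCV pass over a bootstrap replicate of a single feature.
# Features are z-scored inside each training fold; folds whose training set
# contains a single class, or whose feature is degenerate, are skipped.
.loocv_accuracy <- function(x, g, cost, gamma) {
  n <- length(x)
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    xtr <- x[-i]; gtr <- g[-i]
    if (length(unique(gtr)) < 2L) next      # single-class training fold
    mu <- mean(xtr); s <- sd(xtr)
    if (!is.finite(s) || s == 0) {          # zero-variance feature
      score[i] <- 0.5
      next
    }
    m <- e1071::svm(matrix((xtr - mu) / s, ncol = 1), gtr,
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
    pred <- predict(m, matrix((x[i] - mu) / s, ncol = 1))
    score[i] <- as.numeric(pred == g[i])
  }
  mean(score, na.rm = TRUE)
}

#' Bootstrap + leave-one-out SVM accuracy of one parameter
#'
#' Scores how well a single vascular parameter separates two groups with an
#' RBF-kernel SVM. Per bootstrap replicate, animals are resampled with
#' replacement (stratified within group, preserving group sizes, by
#' default); leave-one-out cross-validation over the n resampled animals
#' then scores each held-out animal 100 if classified correctly and 0
#' otherwise, and the replicate accuracy is their mean. The procedure is
#' repeated `n_boot` times (default 1000) and the mean, SD, and percentile
#' 95% CI of the replicate accuracies are reported. Resampling can place
#' identical observations in both training and test folds; this optimistic
#' bias is inherent to the resampling design and left as is.
#'
#' @param table feature table (`animal_id`, `group`, numeric parameters).
#' @param parameter name of the column to score.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed (fixed seed gives bit-identical output).
#' @param cost SVM regularization constant (default 1).
#' @param gamma RBF kernel width; default 1 (features are z-scored per
#'   training fold, so 1 equals `1 / (n_features * var)`).
#' @param stratified resample within groups, preserving group sizes
#'   (default TRUE); FALSE pools all animals.
#' @return one-row data.frame of class `accuracy_report`: `parameter,
#'   mean_accuracy_pct, sd_pct, ci_lo, ci_hi, n_boot, n_animals, flag`.
#' @export
bootstrap_loocv_accuracy <- function(table, parameter, n_boot = 1000L,
                                     seed = 1L, cost = 1, gamma = 1,
                                     stratified = TRUE) {
  if (!parameter %in% names(table))
    stop("parameter column not found: ", parameter, call. = FALSE)
  keep <- !is.na(table[[parameter]])
  dropped <- sum(!keep)
  if (dropped) message(dropped, " row(s) with missing ", parameter, " dropped")
  tab <- table[keep, , drop = FALSE]
  g <- droplevels(factor(tab$group))
  if (nlevels(g) != 2L || any(table(g) < 2L))
    stop("need two groups with at least 2 animals each", call. = FALSE)
  x <- tab[[parameter]]
  n <- length(x)
  flag <- ""
  if (sd(x) == 0) flag <- "zero-variance feature: chance-level by definition"
  set.seed(seed)
  idx_by_group <- split(seq_len(n), g)
  acc <- vapply(seq_len(n_boot), function(b) {
    idx <- if (stratified) {
      unlist(lapply(idx_by_group, function(i) sample(i, length(i),
                                                     replace = TRUE)))
    } else sample(n, n, replace = TRUE)
    if (sd(x) == 0) return(50)
    100 * .loocv_accuracy(x[idx], g[idx], cost, gamma)
  }, numeric(1))
  ci <- unname(quantile(acc, c(0.025, 0.975), type = 7))
  out <- data.frame(parameter = parameter,
                    mean_accuracy_pct = mean(acc), sd_pct = sd(acc),
                    ci_lo = ci[1], ci_hi = ci[2],
                    n_boot = n_boot, n_animals = n, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Score and rank all parameters of a feature panel
#'
#' Runs [bootstrap_loocv_accuracy()] on every parameter column and returns
#' the reports sorted by decreasing mean accuracy, with an optional
#' vein/artery/microvasculature category tag carried through. The result is
#' plot-ready for a radar chart (one spoke per parameter).
#'
#' @param table feature table.
#' @param n_boot,seed,cost,gamma,stratified passed to
#'   [bootstrap_loocv_accuracy()]; every parameter is scored with the same
#'   seed, so duplicated columns produce identical reports.
#' @param categories optional named character vector mapping parameter ->
#'   category; every parameter must be mapped if given.
#' @return `accuracy_report` data.frame, one row per parameter.
#' @export
rank_parameters <- function(table, n_boot = 1000L, seed = 1L,
                            categories = NULL, cost = 1, gamma = 1,
                            stratified = TRUE) {
  params <- setdiff(names(table), c("animal_id", "group"))
  if (!length(params)) stop("no parameter columns", call. = FALSE)
  if (!is.null(categories) && !all(params %in% names(categories)))
    stop("unmapped parameter(s): ",
         paste(setdiff(params, names(categories)), collapse = ", "),
         call. = FALSE)
  reports <- lapply(params, function(p)
    bootstrap_loocv_accuracy(table, p, n_boot = n_boot, seed = seed,
                             cost = cost, gamma = gamma,
                             stratified = stratified))
  out <- do.call(rbind, reports)
  if (!is.null(categories)) out$category <- unname(categories[out$parameter])
  out <- out[order(-out$mean_accuracy_pct), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Per-category accuracy summary
#'
#' Arithmetic mean and SEM of the per-parameter mean accuracies within each
#' category (e.g. vein / artery / microvasculature). Single-parameter
#' categories have no defined SEM and report 0 with a flag.
#'
#' @param reports an `accuracy_report` from [rank_parameters()].
#' @param categories named character vector parameter -> category (not
#'   needed if `reports` already carries a `category` column).
#' @return data.frame: `category, mean_accuracy_pct, sem_pct, n_parameters,
#'   sem_flag`.
#' @export
group_category_summary <- function(reports, categories = NULL) {
  if (is.null(reports$category)) {
    if (is.null(categories))
      stop("no category mapping available", call. = FALSE)
    if (!all(reports$parameter %in% names(categories)))
      stop("unmapped parameter(s): ",
           paste(setdiff(reports$parameter, names(categories)),
                 collapse = ", "), call. = FALSE)
    reports$category <- unname(categories[reports$parameter])
  }
  sp <- split(reports$mean_accuracy_pct, reports$category)
  out <- do.call(rbind, lapply(names(sp), function(cat) {
    v <- sp[[cat]]
    data.frame(category = cat, mean_accuracy_pct = mean(v),
               sem_pct = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
               n_parameters = length(v), sem_flag = length(v) == 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
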