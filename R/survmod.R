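# Clinical evaluation of imaging subtypes: Kaplan-Meier / log-rank, Cox
# proportional hazards (univariate and multivariate), Harrell's C-index
# model comparison and ctDNA-by-subtype crosstabs. Model fitting goes
# through the survival package (Efron tie handling throughout).

#' Kaplan-Meier curves and log-rank test by group
#'
#' @param data data.frame with time/event columns and the grouping column.
#' @param group name of the grouping column.
#' @param time,event column names (default `rfs_time` / `rfs_event`).
#' @return List: `fit` (a [survival::survfit()] object), `chisq`, `df`,
#'   `p` (two-sided log-rank), `groups`.
#' @export
km_logrank <- function(data, group, time = "rfs_time", event = "rfs_event") {
  g <- factor(data[[group]])
  if (nlevels(g) < 2)
    stop("km_logrank: need at least 2 groups in '", group, "'")
  ev_by_g <- tapply(data[[event]], g, sum)
  if (any(ev_by_g == 0))
    warning("km_logrank: group(s) with no events: ",
            paste(names(ev_by_g)[ev_by_g == 0], collapse = ", "),
            " (retained)")
  df <- data.frame(.time = data[[time]], .event = data[[event]], .g = g)
  fit <- survival::survfit(survival::Surv(.time, .event) ~ .g, data = df)
  sd_ <- survival::survdiff(survival::Surv(.time, .event) ~ .g, data = df)
  dof <- nlevels(g) - 1
  p <- stats::pchisq(sd_$chisq, df = dof, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd_$chisq), df = dof, p = p,
       groups = levels(g))
}

#' Cox proportional-hazards fit with tidy output
#'
#' Partial-likelihood fit with Efron tie handling. Categorical covariates are
#' expanded against a declared reference level; for the `subtype` covariate
#' the high-risk group is the reference, so hazard ratios below 1 mean better
#' outcome than high-risk.
#'
#' @param data data.frame of records.
#' @param covariates character vector of covariate column names.
#' @param time,event column names (default `rfs_time` / `rfs_event`).
#' @param reference named list of reference levels for factor covariates
#'   (default `list(subtype = "high")` where applicable).
#' @return List: `fit` (coxph), `table` (data.frame: variable, level, HR,
#'   ci_low, ci_high, p), `n`, `n_events`.
#' @export
cox_fit <- function(data, covariates, time = "rfs_time",
                    event = "rfs_event",
                    reference = list(subtype = "high")) {
  keep <- stats::complete.cases(data[, c(time, event, covariates)])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("cox_fit: excluded ", n_dropped,
            " record(s) with missing covariates (complete-case)")
  df <- data[keep, , drop = FALSE]
  if (sum(df[[event]]) < 10)
    stop("cox_fit: fewer than 10 events (", sum(df[[event]]), ")")
  for (cv in covariates) {
    x <- df[[cv]]
    if (length(unique(x)) < 2)
      stop("cox_fit: constant covariate '", cv, "'")
    if (is.character(x) || is.factor(x)) {
      x <- factor(x)
      if (cv %in% names(reference) && reference[[cv]] %in% levels(x))
        x <- stats::relevel(x, ref = reference[[cv]])
      df[[cv]] <- x
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge|infinite", conditionMessage(w)))
        stop("cox_fit: non-convergence or separation: ",
             conditionMessage(w))
      suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
    })
  sm <- summary(fit)
  tab <- data.frame(
    term = rownames(sm$coefficients),
    hr = sm$coefficients[, "exp(coef)"],
    ci_low = sm$conf.int[, "lower .95"],
    ci_high = sm$conf.int[, "upper .95"],
    p = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  list(fit = fit, table = tab, n = nrow(df), n_events = sum(df[[event]]))
}

#' Harrell's concordance index
#'
#' Probability that, among usable patient pairs, the higher risk score goes
#' with the earlier event; score ties count 0.5. Computed with
#' [survival::concordance()].
#'
#' @param risk_scores finite numeric vector (higher = higher risk).
#' @param time,event survival outcome vectors.
#' @return Scalar C in \[0, 1\].
#' @export
concordance_index <- function(risk_scores, time, event) {
  if (any(!is.finite(risk_scores)))
    stop("concordance_index: non-finite risk score(s)")
  df <- data.frame(t = time, e = event, s = risk_scores)
  cc <- survival::concordance(survival::Surv(t, e) ~ s, data = df,
                              reverse = TRUE)
  if (is.na(cc$concordance)) stop("concordance_index: no usable pairs")
  unname(cc$concordance)
}

#' Compare nested risk models by C-index
#'
#' Fits a Cox model per covariate specification, scores patients by the
#' linear predictor, and reports Harrell's C with a seeded bootstrap CI.
#'
#' @param data data.frame of records (shared patient set).
#' @param specs named list of covariate-name vectors, e.g.
#'   `list(clinical = c(...), full = c(...))`.
#' @param time,event column names.
#' @param n_boot bootstrap replicates for the CI (default 200).
#' @param seed integer RNG seed for the bootstrap.
#' @return Object of class `model_comparison`: data.frame `table`
#'   (model, n_covariates, c_index, ci_low, ci_high) and `deltas` (pairwise
#'   C differences).
#' @export
compare_models <- function(data, specs, time = "rfs_time",
                           event = "rfs_event", n_boot = 200, seed = 1) {
  all_cov <- unique(unlist(specs))
  frac_missing <- vapply(all_cov, function(cv)
    mean(is.na(data[[cv]])), numeric(1))
  if (any(frac_missing > 0.2))
    stop("compare_models: covariate(s) missing for >20% of patients: ",
         paste(all_cov[frac_missing > 0.2], collapse = ", "))
  keep <- stats::complete.cases(data[, c(time, event, all_cov)])
  df <- data[keep, , drop = FALSE]
  res <- lapply(names(specs), function(nm) {
    f <- cox_fit(df, specs[[nm]], time = time, event = event)
    lp <- unname(stats::predict(f$fit, type = "lp"))  # df is complete-case
    t_v <- df[[time]]
    e_v <- df[[event]]
    cidx <- concordance_index(lp, t_v, e_v)
    # bootstrap CI on the concordance of the fitted scores
    set.seed(child_seed(seed, match(nm, names(specs))))
    n <- length(lp)
    bs <- vapply(seq_len(n_boot), function(b) {
      ii <- sample.int(n, n, replace = TRUE)
      tryCatch(concordance_index(lp[ii], t_v[ii], e_v[ii]),
               error = function(e) NA_real_)
    }, numeric(1))
    c(c_index = cidx,
      ci_low = stats::quantile(bs, 0.025, na.rm = TRUE, names = FALSE),
      ci_high = stats::quantile(bs, 0.975, na.rm = TRUE, names = FALSE))
  })
  tab <- data.frame(model = names(specs),
                    n_covariates = vapply(specs, length, integer(1)),
                    do.call(rbind, res), row.names = NULL)
  cmb <- utils::combn(names(specs), 2)
  deltas <- apply(cmb, 2, function(pr)
    tab$c_index[tab$model == pr[2]] - tab$c_index[tab$model == pr[1]])
  names(deltas) <- apply(cmb, 2, paste, collapse = " -> ")
  structure(list(table = tab, deltas = deltas, n = nrow(df)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> n =", x$n, "patients\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' ctDNA status by imaging subtype
#'
#' Row-normalized percentages of each ctDNA category per subtype, with counts
#' alongside, for baseline detection and for clearance status.
#'
#' @param data data.frame with `subtype` plus `ctdna_baseline` and/or
#'   `ctdna_clearance` columns (`NA`/"missing" treated as missing).
#' @param subtype name of the subtype column (default `"subtype"`).
#' @return List of data.frames `baseline` and `clearance` (subtype, category,
#'   n, pct), omitting a table when its column is absent.
#' @export
ctdna_crosstab <- function(data, subtype = "subtype") {
  out <- list()
  for (col in c("ctdna_baseline", "ctdna_clearance")) {
    if (!col %in% names(data)) next
    v <- data[[col]]
    v[v %in% "missing"] <- NA
    ok <- !is.na(v)
    st <- factor(data[[subtype]][ok], levels = unique(data[[subtype]]))
    v <- v[ok]
    tb <- table(st, v)
    empty <- rowSums(tb) == 0
    if (any(empty)) {
      warning("ctdna_crosstab: subtype(s) with all-missing ", col, ": ",
              paste(rownames(tb)[empty], collapse = ", "), " (excluded)")
      tb <- tb[!empty, , drop = FALSE]
    }
    if (nrow(tb) == 0) next
    pct <- 100 * tb / rowSums(tb)
    long <- as.data.frame(tb, stringsAsFactors = FALSE)
    names(long) <- c("subtype", "category", "n")
    long$pct <- as.vector(pct[cbind(long$subtype, long$category)])
    out[[sub("ctdna_", "", col)]] <- long
  }
  if (!length(out)) stop("ctdna_crosstab: no ctDNA columns found")
  out
}
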