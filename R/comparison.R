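#' One-sided Wilcoxon signed-rank test
#'
#' Tests whether the paired values `x` tend to exceed `y` (alternative:
#' x greater). Zero differences are dropped (classic Wilcoxon); absolute
#' differences are midranked. For n remaining pairs up to `exact_max` the
#' p-value comes from the exact null distribution of the positive-rank sum,
#' computed by subset-sum convolution over the (possibly tied) ranks --
#' equivalent to enumerating all 2^n sign assignments. Above that, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest n for which the exact null is used.
#' @param zero_tol Differences with absolute value below this are treated
#'   as zeros and dropped.
#' @return One-sided p-value for median(x - y) > 0; 1 when all differences
#'   are zero.
#' @examples
#' signed_rank_p(2:16, 1:15)  # all 15 positive: 1/2^15
#' @export
signed_rank_p <- function(x, y, exact_max = 25L, zero_tol = 1e-9) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[abs(d) > zero_tol]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))     # midranks doubled -> integers
    total <- sum(r2)
    f <- numeric(total + 1L)           # f[s+1] = #subsets with doubled-rank sum s
    f[1L] <- 1
    for (v in r2) {
      f[(v + 1L):(total + 1L)] <- f[(v + 1L):(total + 1L)] + f[1L:(total + 1L - v)]
    }
    w2 <- as.integer(round(2 * w))
    sum(f[(w2 + 1L):(total + 1L)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - 0.5) / sqrt(sigma2)
    stats::pnorm(z, lower.tail = FALSE)
  }
}

## one performed test: p-value that model a fits better than model b,
## over the per-block log-likelihood rows of one subject
pairwise_p <- function(llb, a, b) signed_rank_p(llb[a, ], llb[b, ])

#' Hierarchical subject-to-model assignment
#'
#' Implements the staged comparison over the constrained five-model space,
#' ordered by the specificity of the models' predictions. Per subject, over
#' the per-block log-likelihoods at the maximum-likelihood parameters:
#' \enumerate{
#'   \item If the dfkl response pattern fits significantly better than the
#'     other four models (four one-sided signed-rank tests, all p < alpha),
#'     the subject is assigned to `drp_dfkl`; otherwise the same is tried
#'     for `drp_lkfd`.
#'   \item Otherwise, if free optimal play beats binarized play and
#'     Q-learning (both p < alpha), the subject is assigned to `fop`.
#'   \item Otherwise, if binarized play beats Q-learning, `bp`.
#'   \item Otherwise, if Q-learning beats free optimal play or binarized
#'     play (either test), `q`.
#'   \item Otherwise `none`.
#' }
#'
#' @param fit An [fit_models()] result containing the five canonical models
#'   `drp_dfkl`, `drp_lkfd`, `fop`, `bp`, `q`.
#' @param alpha Significance threshold per test (no multiple-testing
#'   correction, by design).
#' @return An object of class `srl_assignment`: `$labels` is a data frame
#'   (subject_id, label), `$p_values[[subject_id]]` the named p-values of
#'   every test performed for that subject.
#' @export
assign_subjects <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "srl_fit"))
  need <- c("drp_dfkl", "drp_lkfd", "fop", "bp", "q")
  if (!all(need %in% names(fit$models)))
    stop("fit must contain the five canonical models: ",
         paste(need, collapse = ", "))
  labels <- character(length(fit$ll_blocks))
  pvals <- vector("list", length(fit$ll_blocks))
  ids <- names(fit$ll_blocks)
  for (i in seq_along(ids)) {
    llb <- fit$ll_blocks[[i]]
    p <- c()
    label <- "none"
    for (cand in c("drp_dfkl", "drp_lkfd")) {
      rivals <- setdiff(need, cand)
      pc <- vapply(rivals, function(r) pairwise_p(llb, cand, r), numeric(1))
      names(pc) <- paste0(cand, ">", rivals)
      p <- c(p, pc)
      if (all(pc < alpha)) { label <- cand; break }
    }
    if (label == "none") {
      pc <- c("fop>bp" = pairwise_p(llb, "fop", "bp"),
              "fop>q" = pairwise_p(llb, "fop", "q"))
      p <- c(p, pc)
      if (all(pc < alpha)) label <- "fop"
    }
    if (label == "none") {
      pc <- c("bp>q" = pairwise_p(llb, "bp", "q"))
      p <- c(p, pc)
      if (pc < alpha) label <- "bp"
    }
    if (label == "none") {
      pc <- c("q>fop" = pairwise_p(llb, "q", "fop"),
              "q>bp" = pairwise_p(llb, "q", "bp"))
      p <- c(p, pc)
      if (any(pc < alpha)) label <- "q"
    }
    labels[i] <- label
    pvals[[i]] <- p
  }
  names(pvals) <- ids
  structure(list(labels = data.frame(subject_id = ids, label = labels,
                                     stringsAsFactors = FALSE),
                 p_values = pvals, alpha = alpha),
            class = "srl_assignment")
}

#' @export
print.srl_assignment <- function(x, ...) {
  cat(sprintf("Hierarchical model assignment (p < %g per test):\n", x$alpha))
  print(table(x$labels$label))
  invisible(x)
}

#' Model-recovery matrix
#'
#' Cross-tabulates the generating model of each synthetic subject (from the
#' cohort's ground-truth manifest) against the label assigned by the
#' hierarchical comparison.
#'
#' @param assignment An [assign_subjects()] result.
#' @param manifest Ground-truth manifest, e.g.
#'   `attr(simulate_cohort(spec), "manifest")`.
#' @return Contingency table (true model x assigned label).
#' @export
recovery_matrix <- function(assignment, manifest) {
  m <- merge(assignment$labels, manifest[, c("subject_id", "model")],
             by = "subject_id")
  table(truth = m$model, assigned = m$label)
}

#' Preliminary best-likelihood ranking
#'
#' For each subject, the model with the largest total log-likelihood among
#' all fitted models -- typically the 27-model space of [full_model_set()]
#' (all 24 response orders plus free optimal play, binarized play and
#' Q-learning). No significance testing: the margin over the runner-up can
#' be arbitrarily small, and submitting many models of one class biases the
#' winner towards that class, which is why the staged procedure of
#' [assign_subjects()] is preferred. Ties go to the first model in the
#' fit's enumeration order.
#'
#' @param fit An [fit_models()] result.
#' @return Data frame (subject_id, model, ll_total) of best-ranked models.
#' @export
preliminary_ranking <- function(fit) {
  stopifnot(inherits(fit, "srl_fit"))
  out <- lapply(names(fit$ll_blocks), function(id) {
    d <- fit$fits[fit$fits$subject_id == id, ]
    d <- d[match(names(fit$models), d$model), ]  # fixed enumeration order
    best <- which.max(d$ll_total)                # first maximum wins
    d[best, c("subject_id", "model", "ll_total")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
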