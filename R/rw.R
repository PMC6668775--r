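# Rescorla-Wagner learning: the iterative update rule and the parameter-free
# equilibrium solution over frequency-weighted event tables.

#' Build a frequency-weighted learning event table
#'
#' Each event pairs a set of cues with a set of outcomes and carries a
#' positive weight (a token frequency: one event type per word, weighted by
#' how often it occurs). The table indexes all cues and outcomes it contains.
#'
#' @param cues List of character vectors, one cue set per event.
#' @param outcomes List of character vectors, one outcome set per event.
#' @param weights Positive numeric weights, recycled to the number of events.
#' @return An object of class `ndra_events`.
#' @export
#' @examples
#' ev <- event_table(list(c("a"), c("a", "b")), list("O", "O"), c(1, 3))
#' conditional_probs(ev)$cue_cue
event_table <- function(cues, outcomes, weights = 1) {
  if (!is.list(cues)) cues <- list(cues)
  if (!is.list(outcomes)) outcomes <- list(outcomes)
  if (length(cues) != length(outcomes)) {
    stop("`cues` and `outcomes` must have one entry per event", call. = FALSE)
  }
  n <- length(cues)
  if (n == 0L) stop("event table must contain at least one event", call. = FALSE)
  weights <- rep_len(as.numeric(weights), n)
  if (anyNA(weights) || any(weights <= 0)) {
    stop("event weights must be positive", call. = FALSE)
  }
  cues <- lapply(cues, function(x) unique(as.character(x)))
  outcomes <- lapply(outcomes, function(x) unique(as.character(x)))
  if (any(vapply(cues, length, 1L) == 0L)) {
    stop("every event needs at least one cue", call. = FALSE)
  }
  structure(
    list(
      cues = cues,
      outcomes = outcomes,
      weights = weights,
      cue_index = sort(unique(unlist(cues)), method = "radix"),
      outcome_index = sort(unique(unlist(outcomes)), method = "radix")
    ),
    class = "ndra_events"
  )
}

#' @export
print.ndra_events <- function(x, ...) {
  cat("<ndra_events> ", length(x$weights), " events, ",
      length(x$cue_index), " cues, ", length(x$outcome_index), " outcomes\n",
      sep = "")
  invisible(x)
}

# Sparse incidence matrices: cues x events and outcomes x events.
.incidence <- function(sets, index, n_events) {
  lens <- vapply(sets, length, 1L)
  Matrix::sparseMatrix(
    i = match(unlist(sets), index),
    j = rep.int(seq_len(n_events), lens),
    x = 1,
    dims = c(length(index), n_events)
  )
}

#' Conditional co-occurrence probabilities of an event table
#'
#' Computes the weighted conditional probability matrices that drive the
#' equilibrium solution: `Pr(Cj | Ci)`, the probability that cue `Cj` is
#' present given that cue `Ci` is, and `Pr(Ok | Ci)` for outcomes. Both are
#' ratios of summed event weights, so `Pr(Ci | Ci) = 1`.
#'
#' @param events An `ndra_events` table.
#' @return List with matrices `cue_cue` (cues x cues) and `cue_outcome`
#'   (cues x outcomes), with dimnames.
#' @export
conditional_probs <- function(events) {
  stopifnot(inherits(events, "ndra_events"))
  n <- length(events$weights)
  A <- .incidence(events$cues, events$cue_index, n)
  B <- .incidence(events$outcomes, events$outcome_index, n)
  Aw <- A %*% Matrix::Diagonal(x = events$weights)
  M <- as.matrix(Aw %*% Matrix::t(A))   # joint cue-cue weight
  CO <- as.matrix(Aw %*% Matrix::t(B))  # joint cue-outcome weight
  marg <- diag(M)
  if (any(marg <= 0)) {
    stop("cue(s) with zero total weight: ",
         paste(events$cue_index[marg <= 0], collapse = ", "), call. = FALSE)
  }
  cue_cue <- M / marg
  cue_outcome <- CO / marg
  dimnames(cue_cue) <- list(events$cue_index, events$cue_index)
  dimnames(cue_outcome) <- list(events$cue_index, events$outcome_index)
  list(cue_cue = cue_cue, cue_outcome = cue_outcome)
}

#' Equilibrium Rescorla-Wagner association strengths
#'
#' Solves, for every outcome `k`, the linear system
#' `Pr(Ok | Ci) - sum_j Pr(Cj | Ci) Vjk = 0` whose solution gives the
#' asymptotic association strengths of the Rescorla-Wagner learning rule.
#' The solution is parameter-free: it depends only on the distributional
#' properties of the events. Each outcome column is solved independently of
#' all others (the "naive" independence assumption), which here amounts to a
#' single multi-column solve.
#'
#' Rank-deficient systems, which arise whenever cues are perfectly
#' correlated (e.g. the two demi-syllables of a word that always co-occur),
#' are resolved by the minimum-norm least-squares solution via the
#' Moore-Penrose pseudoinverse; this is deterministic and invariant to cue
#' order.
#'
#' @param events An `ndra_events` table.
#' @param tol Maximum admissible residual of the equilibrium equations on a
#'   full-rank system.
#' @return A cue x outcome weight matrix with a `"residual"` attribute
#'   (the maximum absolute residual of the equilibrium equations).
#' @export
#' @examples
#' # blocking: A alone predicts O; B adds nothing and learns V = 0
#' ev <- event_table(list("a", c("a", "b")), list("O", "O"), c(2, 5))
#' solve_equilibrium(ev)
solve_equilibrium <- function(events, tol = 1e-8) {
  cp <- conditional_probs(events)
  C <- cp$cue_cue
  P <- cp$cue_outcome
  qrC <- qr(C)
  full_rank <- qrC$rank == ncol(C)
  V <- if (full_rank) {
    solve(qrC, P)
  } else {
    MASS::ginv(C) %*% P
  }
  residual <- max(abs(C %*% V - P))
  if (full_rank && residual > tol) {
    stop("equilibrium solver failed: residual ", format(residual),
         " exceeds tolerance ", format(tol), " on a full-rank system",
         call. = FALSE)
  }
  dimnames(V) <- list(events$cue_index, events$outcome_index)
  attr(V, "residual") <- residual
  attr(V, "full_rank") <- full_rank
  V
}

#' Rescorla-Wagner learning parameters
#'
#' Standard values: asymptote `lambda = 1`, uniform cue salience `alpha`,
#' and equal learning rates for outcome-present and outcome-absent trials
#' (`beta1 = beta2`).
#'
#' @param lambda Asymptote of associative strength (> 0).
#' @param alpha Cue salience, uniform across cues.
#' @param beta1 Learning rate when the outcome is present, in (0, 1].
#' @param beta2 Learning rate when the outcome is absent, in (0, 1].
#' @return List of class `ndra_rw_params`.
#' @export
rw_params <- function(lambda = 1, alpha = 1, beta1 = 0.1, beta2 = beta1) {
  stopifnot(lambda > 0, alpha > 0,
            beta1 > 0, beta1 <= 1, beta2 > 0, beta2 <= 1)
  structure(list(lambda = lambda, alpha = alpha, beta1 = beta1, beta2 = beta2),
            class = "ndra_rw_params")
}

#' One Rescorla-Wagner update step
#'
#' Applies the discrete learning rule for a single event: for every cue
#' present in the event and every outcome `O`, the association changes by
#' `alpha * beta1 * (lambda - sum V)` if `O` is present and by
#' `alpha * beta2 * (0 - sum V)` if it is absent, where the sum runs over
#' the present cues. Absent cues are unchanged.
#'
#' @param weights Cue x outcome weight matrix with dimnames.
#' @param cues Character vector of cues present in the event.
#' @param outcomes Character vector of outcomes present in the event.
#' @param params An [rw_params()] object.
#' @return The updated weight matrix.
#' @export
rw_update <- function(weights, cues, outcomes, params = rw_params()) {
  idx <- match(unique(cues), rownames(weights))
  if (anyNA(idx)) {
    stop("cue(s) not indexed in weight matrix: ",
         paste(unique(cues)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out_idx <- match(unique(outcomes), colnames(weights))
  if (anyNA(out_idx)) {
    stop("outcome(s) not indexed in weight matrix: ",
         paste(unique(outcomes)[is.na(out_idx)], collapse = ", "),
         call. = FALSE)
  }
  present <- logical(ncol(weights))
  present[out_idx] <- TRUE
  total <- colSums(weights[idx, , drop = FALSE])
  delta <- params$alpha *
    ifelse(present,
           params$beta1 * (params$lambda - total),
           params$beta2 * (0 - total))
  weights[idx, ] <- weights[idx, , drop = FALSE] +
    rep(delta, each = length(idx))
  weights
}

#' Iterative Rescorla-Wagner learning over sampled trials
#'
#' The trial-level counterpart of [solve_equilibrium()]: events are sampled
#' with probability proportional to their weights and the weight matrix is
#' updated by the discrete learning rule on each trial. With a small
#' learning rate and many trials the result converges to the equilibrium
#' solution, which makes this the independent oracle for the solver.
#'
#' @param events An `ndra_events` table.
#' @param params An [rw_params()] object.
#' @param n_trials Number of learning trials (0 returns the all-zero matrix).
#' @param seed Integer seed; identical seeds give identical trajectories.
#'   The caller's RNG state is left untouched.
#' @param tail_average Fraction of final trials to average over (0 returns
#'   the last-trial matrix). With a constant learning rate the weights
#'   fluctuate around the equilibrium at stationarity; because the update
#'   is linear in the weights, the stationary mean equals the equilibrium
#'   exactly, so averaging the trajectory tail is an unbiased
#'   variance-reduced estimate of the asymptotic state.
#' @return Cue x outcome weight matrix.
#' @export
simulate_learning <- function(events, params = rw_params(), n_trials, seed = 1L,
                              tail_average = 0) {
  stopifnot(tail_average >= 0, tail_average < 1)
  stopifnot(inherits(events, "ndra_events"), n_trials >= 0)
  nc <- length(events$cue_index)
  nk <- length(events$outcome_index)
  V <- matrix(0, nc, nk, dimnames = list(events$cue_index, events$outcome_index))
  if (n_trials == 0L) return(V)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  draws <- sample.int(length(events$weights), n_trials, replace = TRUE,
                      prob = events$weights)

  cue_idx <- lapply(events$cues, match, events$cue_index)
  pres <- matrix(FALSE, length(events$weights), nk)
  for (e in seq_along(events$outcomes)) {
    pres[e, match(events$outcomes[[e]], events$outcome_index)] <- TRUE
  }
  ab1 <- params$alpha * params$beta1
  ab2 <- params$alpha * params$beta2
  lambda <- params$lambda
  avg_from <- if (tail_average > 0) {
    n_trials - floor(tail_average * n_trials) + 1L
  } else {
    n_trials + 1L
  }
  Vsum <- if (tail_average > 0) V else NULL
  n_avg <- 0L
  for (t in seq_len(n_trials)) {
    e <- draws[t]
    idx <- cue_idx[[e]]
    total <- .colSums(V[idx, , drop = FALSE], length(idx), nk)
    p <- pres[e, ]
    delta <- ab1 * (lambda - total) * p - ab2 * total * (!p)
    V[idx, ] <- V[idx, , drop = FALSE] + rep(delta, each = length(idx))
    if (t >= avg_from) {
      Vsum <- Vsum + V
      n_avg <- n_avg + 1L
    }
  }
  if (n_avg > 0L) Vsum / n_avg else V
}

#' Outcome activations given a set of active cues
#'
#' The activation of an outcome is the sum of the association strengths from
#' the active cues to that outcome, plus a small back-off constant that
#' keeps downstream multiplicative latency formulas away from zero. Cues
#' absent from the weight matrix contribute nothing, so an input made
#' entirely of unknown cues activates every outcome at the back-off level.
#'
#' @param weights Cue x outcome weight matrix with dimnames.
#' @param cues Character vector of active cues.
#' @param backoff Non-negative constant added to every activation
#'   (default 0.01).
#' @return Named numeric vector of activations, one per outcome.
#' @export
activation <- function(weights, cues, backoff = 0.01) {
  stopifnot(backoff >= 0)
  idx <- match(unique(cues), rownames(weights))
  idx <- idx[!is.na(idx)]
  a <- .colSums(weights[idx, , drop = FALSE], length(idx), ncol(weights)) +
    backoff
  names(a) <- colnames(weights)
  a
}
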