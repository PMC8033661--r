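## Jones-Taylor-Thornton (JTT) amino-acid replacement model.
##
## One source of truth for both the sequence simulator and the ML distance
## estimator: exchangeabilities and stationary frequencies are taken from the
## published JTT model as distributed with phangorn, assembled here into a
## normalised instantaneous rate matrix (1 expected substitution per site per
## unit time at stationarity) with a cached eigendecomposition.

#' Amino-acid order used throughout the package
#'
#' The 20 standard residues in the order of the substitution model's
#' rate matrix and of every frequency/profile matrix.
#' @export
AA_LEVELS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.model_cache <- new.env(parent = emptyenv())

#' Amino-acid substitution model
#'
#' Returns the rate matrix `Q` (rows = from, cols = to; scaled so that the
#' expected substitution rate at stationarity is 1 per site per unit time),
#' stationary frequencies `bf`, and an eigendecomposition used to compute
#' transition matrices.
#'
#' @param model `"jtt"` for the Jones-Taylor-Thornton empirical model, or
#'   `"poisson_uniform"` for the Poisson model with uniform frequencies
#'   (all exchangeabilities equal).
#' @return list with elements `Q`, `bf`, `eig` (eigendecomposition of the
#'   symmetrised rate matrix) and `levels` (amino-acid order).
#' @export
aa_model <- function(model = c("jtt", "poisson_uniform")) {
  model <- match.arg(model)
  if (!is.null(.model_cache[[model]])) return(.model_cache[[model]])
  n <- 20L
  if (model == "jtt") {
    grab <- function() {
      Q <- NULL; bf <- NULL
      f <- utils::getFromNamespace("getModelAA", "phangorn")
      f("JTT", bf = TRUE, Q = TRUE)  # assigns Q and bf into this frame
      list(ex = Q, bf = bf)
    }
    got <- grab()
    ex <- got$ex       # lower-triangle exchangeabilities, length 190
    bf <- got$bf
  } else {
    ex <- rep(1, n * (n - 1) / 2)
    bf <- rep(1 / n, n)
  }
  S <- matrix(0, n, n, dimnames = list(AA_LEVELS, AA_LEVELS))
  S[lower.tri(S)] <- ex
  S <- S + t(S)
  Q <- S %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(bf * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(AA_LEVELS, AA_LEVELS)
  ## symmetrise for a stable eigendecomposition:
  ## B = D^{1/2} Q D^{-1/2} is symmetric when Q is time-reversible
  D <- sqrt(bf)
  B <- diag(D) %*% Q %*% diag(1 / D)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  out <- list(Q = Q, bf = stats::setNames(bf, AA_LEVELS),
              eig = list(values = eig$values,
                         right = diag(1 / D) %*% eig$vectors,
                         left = t(eig$vectors) %*% diag(D)),
              levels = AA_LEVELS, name = model)
  .model_cache[[model]] <- out
  out
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model result of [aa_model()].
#' @param t branch length in expected substitutions per site (>= 0).
#' @return 20 x 20 stochastic matrix, rows = ancestral residue.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(is.finite(t), t >= 0)
  P <- model$eig$right %*% (exp(model$eig$values * t) * model$eig$left)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$levels, model$levels)
  P
}

#' Expected proportion of observed differences at divergence t
#'
#' The probability that the two ends of a branch of length `t` show
#' different residues, under the model at stationarity.
#'
#' @inheritParams transition_matrix
#' @export
expected_p_distance <- function(model, t) {
  P <- transition_matrix(model, t)
  1 - sum(model$bf * diag(P))
}
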