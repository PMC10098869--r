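#' Fit the full decoder cascade (REW-PLS + SR-UKF)
#'
#' Fits the recursive exponentially weighted PLS stage on lag-expanded
#' features versus extended kinematics, selects the number of latent
#' components at the knee of the cross-validated correlation curve (unless
#' `A` is given), projects the training features into the latent space and
#' fits the square-root UKF stage on the latent/kinematics pair. Both stages
#' are refit together whenever the training pool changes.
#'
#' @param Y lag-expanded features `d x n`.
#' @param Z extended kinematics `6 x n` (see [extend_kinematics()]).
#' @param A latent components; `NULL` selects via [select_components()].
#' @param lambda forgetting factor of the covariance recursion.
#' @param A_max,folds passed to [select_components()].
#' @param state optional pre-accumulated [cov_state()] for the PLS stage
#'   (the raw `Y`, `Z` are still required for the UKF stage).
#' @param ... passed to [srukf()].
#' @return object of class `traj_decoder` with elements `pls`, `ukf`, `A`.
#' @export
traj_decoder <- function(Y, Z, A = NULL, lambda = 1, A_max = 50L,
                         folds = 10L, state = NULL, ...) {
  .assert_matrix(Y)
  .assert_matrix(Z)
  if (is.null(A)) {
    A <- select_components(Y, Z, A_max = A_max, folds = folds,
      lambda = lambda
    )$A
  }
  if (is.null(state)) {
    state <- cov_update(cov_state(nrow(Y), nrow(Z), lambda), Y, Z)
  }
  pls <- rewpls_fit(state, A)
  E <- predict(pls, Y, type = "scores")
  ukf <- srukf(E, Z, ...)
  structure(
    list(pls = pls, ukf = ukf, A = pls$A, lambda = lambda),
    class = "traj_decoder"
  )
}

#' Decode kinematics from features
#'
#' @param object a `traj_decoder`.
#' @param newdata features `d x n`.
#' @param ... unused.
#' @return `6 x n` decoded extended kinematics; the raw PLS predictions are
#'   attached as attribute `pls`.
#' @export
predict.traj_decoder <- function(object, newdata, ...) {
  pr <- predict(object$pls, newdata, type = "both")
  zhat <- suppressWarnings(predict(object$ukf, pr$scores))
  attr(zhat, "pls") <- pr$response
  zhat
}

#' @export
print.traj_decoder <- function(x, ...) {
  cat("Trajectory decoder cascade\n  ")
  print(x$pls)
  cat("  ")
  print(x$ukf)
  invisible(x)
}
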