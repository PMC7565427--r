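# Pluggable regressors for the benchmark. A regressor is a list with
#   $fit(xTrain, yTrain, xVal, yVal) -> model   (early stopping on val)
#   $predict(model, x) -> predictions
#   $name
# The gradient-boosting internals are deliberately not part of the contract;
# the gene selection method, not the regressor, is what is being compared.

#' Gradient-boosted tree regressor (xgboost)
#'
#' Squared-error boosting with early stopping on the validation fold: stops
#' when the validation loss fails to improve for
#' \code{earlyStoppingRounds} steps, otherwise runs \code{nrounds} steps
#' (defaults 1500 / 150; a large-data profile would use 5000 / 500). All
#' other parameters keep the library defaults.
#'
#' @param nrounds maximal boosting steps
#' @param earlyStoppingRounds early-stopping patience
#' @param nthread threads used by the booster
#' @return a regressor list usable by \code{\link{runBenchmark}}
#' @export
xgboostRegressor <- function(nrounds = 1500L, earlyStoppingRounds = 150L,
                             nthread = 1L) {
  list(
    name = "xgboost",
    fit = function(xTrain, yTrain, xVal, yVal) {
      dtr <- xgboost::xgb.DMatrix(as.matrix(xTrain), label = yTrain)
      dva <- xgboost::xgb.DMatrix(as.matrix(xVal), label = yVal)
      xgboost::xgb.train(
        params = xgboost::xgb.params(objective = "reg:squarederror",
                                     nthread = nthread),
        data = dtr, nrounds = nrounds, evals = list(val = dva),
        early_stopping_rounds = earlyStoppingRounds, verbose = 0)
    },
    predict = function(model, x) stats::predict(model, as.matrix(x)))
}

#' Ordinary least-squares regressor
#'
#' A linear baseline regressor (no early stopping; the validation fold is
#' ignored). Useful for fast deterministic tests of the benchmark plumbing.
#'
#' @return a regressor list usable by \code{\link{runBenchmark}}
#' @export
linearRegressor <- function() {
  list(
    name = "linear",
    fit = function(xTrain, yTrain, xVal, yVal) {
      x <- cbind(1, as.matrix(xTrain))
      list(coef = stats::lm.fit(x, yTrain)$coefficients)
    },
    predict = function(model, x) {
      b <- model$coef
      b[is.na(b)] <- 0
      as.vector(cbind(1, as.matrix(x)) %*% b)
    })
}
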