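# predict() methods for the helper predictors. Registered here so test
# cohorts can be explained through the same generic the package uses.

predict.test_additive <- function(object, newdata, ...) {
  out <- rep(object$intercept, nrow(newdata))
  for (f in names(object$slopes)) {
    out <- out + object$slopes[[f]] * newdata[[f]]
  }
  out
}

predict.test_interacting <- function(object, newdata, ...) {
  f <- object$features
  stats::plogis(newdata[[f[1]]] * newdata[[f[2]]] +
                  0.5 * newdata[[f[1]]] - 0.3 * newdata[[f[2]]])
}

# Make the methods visible to dispatch from inside the package namespace.
registerS3method("predict", "test_additive", predict.test_additive,
                 envir = asNamespace("stats"))
registerS3method("predict", "test_interacting", predict.test_interacting,
                 envir = asNamespace("stats"))
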