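# Independent brute-force oracle for the leave-one-out protocol: refits every
# fold from scratch by solving the normal equations directly (the package
# itself uses a QR path).
brute_force_loo <- function(records, kind, element_order) {
  X <- design_matrix(kind, records, element_order)
  y <- records$dg_exp - records$dg_method
  n <- nrow(X)
  pred <- numeric(n)
  coefs <- matrix(NA_real_, n, ncol(X))
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y[-i])
    coefs[i, ] <- beta
    pred[i] <- records$dg_method[i] + drop(X[i, , drop = FALSE] %*% beta)
  }
  list(pred = setNames(pred, records$id), coefs = coefs)
}
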