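# Hierarchical bivariate robust regression of (d13C, d15N).
# Likelihood: multivariate Student-t via its gamma scale-mixture
# representation; mean = species intercept + species-nested factor slopes
# (season cold=1, sex male=1, stage juvenile=1); Laplace (double
# exponential) shrinkage prior on the slopes with a shared, learned scale
# per factor and axis; species covariance through a separation strategy
# (half-normal axis scales, LKJ(2)-equivalent Beta prior on the
# correlation).
model {
  for (i in 1:N) {
    lam[i] ~ dgamma(halfnu, halfnu)
    for (j in 1:2) {
      mu[i, j] <- alpha[sp[i], j] + inprod(beta[sp[i], 1:F, j], x[i, 1:F])
    }
    y[i, 1:2] ~ dmnorm(mu[i, 1:2], lam[i] * Tau[sp[i], 1:2, 1:2])
  }
  halfnu <- nu / 2
  nu ~ dgamma(2, 0.1) T(2, )
  for (s in 1:S) {
    for (j in 1:2) {
      alpha[s, j] ~ dnorm(mu_alpha[j], prec_alpha[j])
      for (f in 1:F) {
        beta[s, f, j] ~ ddexp(0, 1 / b[f, j])
      }
    }
    sig[s, 1] ~ dnorm(0, prec_sig) T(0, )
    sig[s, 2] ~ dnorm(0, prec_sig) T(0, )
    r01[s] ~ dbeta(2, 2)
    rho[s] <- 2 * r01[s] - 1
    det2[s] <- pow(sig[s, 1] * sig[s, 2], 2) * (1 - pow(rho[s], 2))
    Tau[s, 1, 1] <- pow(sig[s, 2], 2) / det2[s]
    Tau[s, 2, 2] <- pow(sig[s, 1], 2) / det2[s]
    Tau[s, 1, 2] <- -rho[s] * sig[s, 1] * sig[s, 2] / det2[s]
    Tau[s, 2, 1] <- Tau[s, 1, 2]
  }
  for (j in 1:2) {
    mu_alpha[j] ~ dnorm(gm[j], 1 / pow(alpha_hyper_sd, 2))
    sd_alpha[j] ~ dnorm(0, 1 / pow(alpha_hyper_sd, 2)) T(0, )
    prec_alpha[j] <- 1 / pow(sd_alpha[j], 2)
  }
  for (f in 1:F) {
    for (j in 1:2) {
      b[f, j] ~ dnorm(0, 1 / pow(laplace_hyper_sd, 2)) T(0, )
    }
  }
  prec_sig <- 1 / pow(cov_scale, 2)
}
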