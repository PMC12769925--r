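# JAGS model code for the three modelling strategies.
#
# Conventions shared by all three:
#  * arms are fitted separately, so no treatment index appears;
#  * costs enter scaled to thousands of currency units;
#  * regression coefficients ~ N(0, 1/prec.coef), sds half-normal,
#    gamma shapes exponential (all passed as data, see prior_data());
#  * missing outcomes are NA in the data and sampled by the sampler,
#    which is what makes the missingness handling "ALL" rather than
#    an imputation step;
#  * marginal means are computed inside the model by averaging the
#    individual predicted means over the sample.

# cost likelihood chunks, shared by S1 (index i) and S2 (index i,j)
cost_chunk_s1 <- function(family) {
  switch(family,
    gamma = list(
      lik = "
    tc[i] ~ dgamma(sh.tc, rt.tc[i])
    rt.tc[i] <- sh.tc / mean.tc[i]
    log(mean.tc[i]) <- beta0 + beta1 * (e[i] - ebar)
    ll.tc[i] <- logdensity.gamma(tc[i], sh.tc, rt.tc[i])",
      prior = "
  sh.tc ~ dexp(shape.rate)"),
    lognormal = list(
      lik = "
    tc[i] ~ dlnorm(lmu.tc[i], tau.tc)
    lmu.tc[i] <- beta0 + beta1 * (e[i] - ebar)
    mean.tc[i] <- exp(lmu.tc[i] + 1 / (2 * tau.tc))
    ll.tc[i] <- logdensity.lnorm(tc[i], lmu.tc[i], tau.tc)",
      prior = "
  tau.tc <- pow(sd.tc, -2)
  sd.tc ~ dnorm(0, prec.sd) T(0,)"),
    normal = list(
      lik = "
    tc[i] ~ dnorm(mean.tc[i], tau.tc)
    mean.tc[i] <- beta0 + beta1 * (e[i] - ebar)
    ll.tc[i] <- logdensity.norm(tc[i], mean.tc[i], tau.tc)",
      prior = "
  tau.tc <- pow(sd.tc, -2)
  sd.tc ~ dnorm(0, prec.sd) T(0,)"),
    stop("unknown cost family: ", family, call. = FALSE)
  )
}

# S1: marginal normal model for QALYs (baseline-utility adjusted) and a
# conditional cost model given the QALY (log link under gamma/lognormal).
jags_model_s1 <- function(cost_family = "gamma", covariate_baseline = TRUE) {
  ck <- cost_chunk_s1(cost_family)
  phi_e <- if (covariate_baseline) {
    "phi.e[i] <- alpha0 + alpha1 * (u0[i] - u0bar)"
  } else {
    "phi.e[i] <- alpha0"
  }
  alpha1_prior <- if (covariate_baseline) "\n  alpha1 ~ dnorm(0, prec.coef)" else ""
  u0_model <- if (covariate_baseline) "
    u0[i] ~ dnorm(mu.u0, tau.u0)" else ""
  u0_prior <- if (covariate_baseline) "
  mu.u0 ~ dnorm(0, prec.coef)
  tau.u0 <- pow(sd.u0, -2)
  sd.u0 ~ dnorm(0, prec.sd) T(0,)" else ""
  paste0("
model {
  for (i in 1:n) {", u0_model, "
    e[i] ~ dnorm(phi.e[i], tau.e)
    ", phi_e, "
    ll.e[i] <- logdensity.norm(e[i], phi.e[i], tau.e)", ck$lik, "
  }
  mu.e <- mean(phi.e[1:n])
  mu.tc <- mean(mean.tc[1:n])
  alpha0 ~ dnorm(0, prec.coef)", alpha1_prior, "
  beta0 ~ dnorm(0, prec.coef)
  beta1 ~ dnorm(0, prec.coef)
  tau.e <- pow(sd.e, -2)
  sd.e ~ dnorm(0, prec.sd) T(0,)", u0_prior, ck$prior, "
}
")
}

# S2: longitudinal conditional models -- utility at j given utility at j-1
# and the contemporaneous cost; cost at j given utility and cost at j-1.
# Baseline utility and cost are modelled marginally.
jags_model_s2 <- function(cost_family = "gamma") {
  lik <- switch(cost_family,
    gamma = list(
      base = "
    c[i, 1] ~ dgamma(sh.c[1], rt.c[i, 1])
    rt.c[i, 1] <- sh.c[1] / mean.c[i, 1]
    log(mean.c[i, 1]) <- b0[1]
    ll.c[i, 1] <- logdensity.gamma(c[i, 1], sh.c[1], rt.c[i, 1])",
      fup = "
      c[i, j] ~ dgamma(sh.c[j], rt.c[i, j])
      rt.c[i, j] <- sh.c[j] / mean.c[i, j]
      log(mean.c[i, j]) <- b0[j] + b1[j] * (u[i, j - 1] - ubar[j - 1]) + b2[j] * (c[i, j - 1] - cbar[j - 1])
      ll.c[i, j] <- logdensity.gamma(c[i, j], sh.c[j], rt.c[i, j])",
      prior = "
    sh.c[j] ~ dexp(shape.rate)"),
    normal = list(
      base = "
    c[i, 1] ~ dnorm(mean.c[i, 1], tau.c[1])
    mean.c[i, 1] <- b0[1]
    ll.c[i, 1] <- logdensity.norm(c[i, 1], mean.c[i, 1], tau.c[1])",
      fup = "
      c[i, j] ~ dnorm(mean.c[i, j], tau.c[j])
      mean.c[i, j] <- b0[j] + b1[j] * (u[i, j - 1] - ubar[j - 1]) + b2[j] * (c[i, j - 1] - cbar[j - 1])
      ll.c[i, j] <- logdensity.norm(c[i, j], mean.c[i, j], tau.c[j])",
      prior = "
    tau.c[j] <- pow(sd.c[j], -2)
    sd.c[j] ~ dnorm(0, prec.sd) T(0,)"),
    stop("unknown cost family for strategy S2: ", cost_family, call. = FALSE)
  )
  paste0("
model {
  for (i in 1:n) {
    u[i, 1] ~ dnorm(mu.u0, tau.u0)
    ll.u[i, 1] <- logdensity.norm(u[i, 1], mu.u0, tau.u0)", lik$base, "
    for (j in 2:Jp1) {
      u[i, j] ~ dnorm(phi.u[i, j], tau.u[j])
      phi.u[i, j] <- a0[j] + a1[j] * (u[i, j - 1] - ubar[j - 1]) + a2[j] * (c[i, j] - cbar[j])
      ll.u[i, j] <- logdensity.norm(u[i, j], phi.u[i, j], tau.u[j])", lik$fup, "
    }
  }
  mu.u[1] <- mu.u0
  mu.c[1] <- mean(mean.c[1:n, 1])
  for (j in 2:Jp1) {
    mu.u[j] <- mean(phi.u[1:n, j])
    mu.c[j] <- mean(mean.c[1:n, j])
  }
  mu.e <- sum((mu.u[2:Jp1] + mu.u[1:(Jp1 - 1)]) * delta[1:(Jp1 - 1)] / 2)
  mu.tc <- sum(mu.c[2:Jp1])
  mu.u0 ~ dnorm(0, prec.coef)
  tau.u0 <- pow(sd.u0, -2)
  sd.u0 ~ dnorm(0, prec.sd) T(0,)
  b0[1] ~ dnorm(0, prec.coef)
  for (j in 2:Jp1) {
    a0[j] ~ dnorm(0, prec.coef)
    a1[j] ~ dnorm(0, prec.coef)
    a2[j] ~ dnorm(0, prec.coef)
    b0[j] ~ dnorm(0, prec.coef)
    b1[j] ~ dnorm(0, prec.coef)
    b2[j] ~ dnorm(0, prec.coef)
    tau.u[j] <- pow(sd.u[j], -2)
    sd.u[j] ~ dnorm(0, prec.sd) T(0,)
  }
  for (j in 1:Jp1) {", lik$prior, "
  }
}
")
}

# S3: per-service hurdle. d[i,k] = 1 marks a structural zero over the whole
# profile (logistic in centred baseline utility); the continuous normal
# component, with AR-style conditioning on the previous visit's utility and
# usage, applies only to potentially non-structural individuals (those with
# any positive observation or an undetermined profile), indexed by
# idx[1:m[k], k]. A high-precision spike at 0 stands in for the point mass
# when d is latent, so an all-zero-but-incomplete profile updates d.
# Marginal rates combine as mu.hru = (1 - pi) * mu.pos per draw.
jags_model_s3 <- function() {
"
model {
  for (i in 1:n) {
    u[i, 1] ~ dnorm(mu.u0, tau.u0)
    u0c[i] <- u[i, 1] - u0bar
    for (j in 2:Jp1) {
      u[i, j] ~ dnorm(phi.u[i, j], tau.u[j])
      phi.u[i, j] <- a0[j] + a1[j] * (u[i, j - 1] - ubar[j - 1])
    }
    for (k in 1:K) {
      d[i, k] ~ dbern(eta[i, k])
      logit(eta[i, k]) <- g0[k] + g1[k] * u0c[i]
    }
  }
  for (k in 1:K) {
    for (q in 1:m[k]) {
      hru[idx[q, k], 1, k] ~ dnorm(mu.h[q, 1, k], tau.eff[q, 1, k])
      mu.h[q, 1, k] <- (1 - d[idx[q, k], k]) * b0[1, k]
      tau.eff[q, 1, k] <- d[idx[q, k], k] * spike + (1 - d[idx[q, k], k]) * tau.h[1, k]
      for (j in 2:Jp1) {
        hru[idx[q, k], j, k] ~ dnorm(mu.h[q, j, k], tau.eff[q, j, k])
        mu.h[q, j, k] <- (1 - d[idx[q, k], k]) *
          (b0[j, k] + b1[j, k] * (u[idx[q, k], j - 1] - ubar[j - 1]) + b2[j, k] * (hru[idx[q, k], j - 1, k] - hbar[j - 1, k]))
        tau.eff[q, j, k] <- d[idx[q, k], k] * spike + (1 - d[idx[q, k], k]) * tau.h[j, k]
      }
    }
    g0[k] ~ dnorm(0, prec.coef)
    g1[k] ~ dnorm(0, prec.coef)
    pi.k[k] <- mean(eta[1:n, k])
    nfree[k] <- m[k] - sum(d[idx[1:m[k], k], k])
    for (j in 1:Jp1) {
      b0[j, k] ~ dnorm(0, prec.coef)
      tau.h[j, k] <- pow(sd.h[j, k], -2)
      sd.h[j, k] ~ dnorm(0, prec.sd) T(0,)
      mu.pos[j, k] <- inprod(1 - d[idx[1:m[k], k], k], mu.h[1:m[k], j, k]) /
        max(nfree[k], 1)
      mu.hru[j, k] <- (1 - pi.k[k]) * mu.pos[j, k]
    }
    for (j in 2:Jp1) {
      b1[j, k] ~ dnorm(0, prec.coef)
      b2[j, k] ~ dnorm(0, prec.coef)
    }
    for (j in 1:Jp1) {
      mu.cjk[j, k] <- price[k] * mu.hru[j, k]
    }
  }
  for (j in 2:Jp1) {
    mu.u[j] <- mean(phi.u[1:n, j])
  }
  for (j in 1:Jp1) {
    mu.c[j] <- sum(mu.cjk[j, 1:K])
  }
  mu.u[1] <- mu.u0
  mu.e <- sum((mu.u[2:Jp1] + mu.u[1:(Jp1 - 1)]) * delta[1:(Jp1 - 1)] / 2)
  mu.tc <- sum(mu.c[2:Jp1])
  mu.u0 ~ dnorm(0, prec.coef)
  tau.u0 <- pow(sd.u0, -2)
  sd.u0 ~ dnorm(0, prec.sd) T(0,)
  for (j in 2:Jp1) {
    a0[j] ~ dnorm(0, prec.coef)
    a1[j] ~ dnorm(0, prec.coef)
    tau.u[j] <- pow(sd.u[j], -2)
    sd.u[j] ~ dnorm(0, prec.sd) T(0,)
  }
}
"
}
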