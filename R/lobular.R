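#' Lobular abundances and the islet-level modelling table
#'
#' Per donor and lobule, each cell type's abundance in the extra-islet space
#' is its count divided by the extra-islet acinar count (normalising for
#' lobule area); cells inside islets are omitted. Abundances are z-normalised
#' within each donor across its lobules; islet pseudotimes are z-normalised
#' across the entire dataset. The reserved "edge" pseudo-lobule (interlobular
#' space) is excluded from modelling, as are lobules with no extra-islet
#' acinar cells (with a warning).
#'
#' @param table Cell table with `lobule_id` and `islet_id` columns (NA
#'   `islet_id` = extra-islet; see [add_islet_ids()] and [assign_lobules()]).
#' @param islets Islet tibble.
#' @param pseudotime Tibble `islet_id`, `pseudotime`.
#' @param vocabulary Cell-type vocabulary.
#' @param acinar_type Acinar label.
#' @param exclude_edge Drop the "edge" pseudo-lobule from modelling.
#' @return A `lobular_abundance`: list with `lobules` (tibble `donor_id`,
#'   `lobule_id`, `n_acinar`, `n_islets`, `mean_pseudotime`, `raw_<type>` and
#'   `z_<type>` columns), `islets` (tibble `islet_id`, `donor_id`,
#'   `lobule_id`, `pseudotime`, `pt_z`), and `excluded` lobule keys.
#' @export
lobular_abundance <- function(table, islets, pseudotime,
                              vocabulary = default_vocabulary(),
                              acinar_type = "acinar", exclude_edge = TRUE) {
  stopifnot(all(c("lobule_id", "islet_id") %in% names(table)))
  extra <- table[is.na(table$islet_id), ]
  types <- vocabulary$type
  counts <- extra |>
    dplyr::count(.data$donor_id, .data$lobule_id, .data$cell_type) |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "n",
                       values_fill = 0L)
  for (t in setdiff(types, names(counts))) counts[[t]] <- 0L
  counts$n_acinar <- counts[[acinar_type]]
  excluded <- counts[counts$n_acinar == 0, c("donor_id", "lobule_id")]
  if (nrow(excluded) > 0) {
    warning("excluding ", nrow(excluded),
            " lobule(s) with zero extra-islet acinar cells")
    counts <- counts[counts$n_acinar > 0, ]
  }
  if (exclude_edge) counts <- counts[counts$lobule_id != "edge", ]
  lob <- counts[, c("donor_id", "lobule_id", "n_acinar")]
  for (t in types) lob[[paste0("raw_", t)]] <- counts[[t]] / counts$n_acinar
  # z-normalise within donor across lobules; a constant column stays 0
  for (t in types) {
    z <- stats::ave(lob[[paste0("raw_", t)]], lob$donor_id, FUN = function(x) {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    })
    lob[[paste0("z_", t)]] <- z
  }

  # islet -> lobule by majority vote of member cells
  memb <- tibble::tibble(
    cell_id = unlist(islets$members),
    islet_id = rep(islets$islet_id, lengths(islets$members)))
  memb$lobule_id <- table$lobule_id[match(memb$cell_id, table$cell_id)]
  islet_lob <- memb |>
    dplyr::count(.data$islet_id, .data$lobule_id) |>
    dplyr::group_by(.data$islet_id) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  isl <- tibble::tibble(islet_id = islets$islet_id,
                        donor_id = islets$donor_id)
  isl$lobule_id <- islet_lob$lobule_id[match(isl$islet_id,
                                             islet_lob$islet_id)]
  isl$pseudotime <- pseudotime$pseudotime[match(isl$islet_id,
                                                pseudotime$islet_id)]
  isl <- isl[!is.na(isl$pseudotime), ]
  isl$pt_z <- as.numeric(scale(isl$pseudotime))

  pt_by_lob <- isl |>
    dplyr::group_by(.data$donor_id, .data$lobule_id) |>
    dplyr::summarise(n_islets = dplyr::n(),
                     mean_pseudotime = mean(.data$pseudotime),
                     .groups = "drop")
  lob <- dplyr::left_join(lob, pt_by_lob, by = c("donor_id", "lobule_id"))
  lob$n_islets[is.na(lob$n_islets)] <- 0L
  structure(list(lobules = lob, islets = isl, excluded = excluded),
            class = "lobular_abundance")
}

# islet-level modelling frame: outcome pt_z, covariate x = lobule z-abundance
.hlm_frame <- function(ab, cell_type) {
  zcol <- paste0("z_", cell_type)
  if (!zcol %in% names(ab$lobules)) stop("unknown cell type: ", cell_type,
                                         call. = FALSE)
  df <- dplyr::inner_join(
    ab$islets,
    ab$lobules[, c("donor_id", "lobule_id", zcol)],
    by = c("donor_id", "lobule_id"))
  names(df)[names(df) == zcol] <- "x"
  df[!is.na(df$lobule_id), ]
}

#' Intraclass correlation of islet pseudotime within lobules
#'
#' REML fit of the random-intercept model `pseudotime ~ 1 + (1 | lobule)`;
#' ICC = tau^2 / (tau^2 + sigma^2), the fraction of pseudotime variance
#' attributable to lobules. 0 means islets within a lobule vary as much as
#' islets overall (no lobular patterning); 1 means lobules are internally
#' synchronised. Lobules with fewer than `min_islets` islets are excluded.
#'
#' @param data A `lobular_abundance`, or a tibble with `pseudotime` and
#'   `lobule_id` columns (one donor's islets).
#' @param donor Restrict to one donor (NULL = all rows pooled).
#' @param min_islets Minimum islets per lobule for inclusion.
#' @return An `hlm_fit` with `tau2`, `sigma2`, `icc`.
#' @export
fit_icc <- function(data, donor = NULL, min_islets = 2) {
  df <- if (inherits(data, "lobular_abundance")) data$islets else data
  if (!is.null(donor)) df <- df[df$donor_id == donor, ]
  df <- df[!is.na(df$lobule_id) & df$lobule_id != "edge", ]
  keep <- names(which(table(df$lobule_id) >= min_islets))
  df <- df[df$lobule_id %in% keep, ]
  if (length(unique(df$lobule_id)) < 2) {
    stop("need at least 2 lobules with >= ", min_islets, " islets",
         call. = FALSE)
  }
  fit <- lme4::lmer(pseudotime ~ 1 + (1 | lobule_id), data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "lobule_id"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  new_hlm_fit(type = "icc", model = fit,
              fixed = tibble::tibble(term = "(Intercept)",
                                     estimate = unname(lme4::fixef(fit)),
                                     se = NA, df = NA, p_value = NA),
              tau2 = tau2, sigma2 = sigma2, icc = tau2 / (tau2 + sigma2),
              n_obs = nrow(df), n_groups = length(unique(df$lobule_id)))
}

#' Two-level hierarchical model of lobular composition vs islet pseudotime
#'
#' Within one donor, REML fit of
#' `pt_z ~ x + (1 | lobule)` with `x` the donor-z-normalised extra-islet
#' lobular abundance of `cell_type`; the slope is reported with Satterthwaite
#' degrees of freedom and a two-sided p-value (no multiplicity correction).
#' With `donor = NULL` the model is fitted per donor and a summary tibble is
#' returned.
#'
#' @param ab A `lobular_abundance`.
#' @param cell_type Cell type whose lobular abundance is the covariate.
#' @param donor Donor id, or NULL for all donors.
#' @param min_lobules Minimum lobules with islets per donor.
#' @return An `hlm_fit` (single donor) or a tibble of per-donor slope rows
#'   with attribute `fits`.
#' @export
fit_two_level_hlm <- function(ab, cell_type, donor = NULL, min_lobules = 5) {
  df_all <- .hlm_frame(ab, cell_type)
  fit_one <- function(df, label) {
    nlob <- length(unique(df$lobule_id))
    if (nlob < 2) stop("random intercept inestimable with ", nlob, " lobule(s)",
                       call. = FALSE)
    if (nlob < min_lobules) {
      stop("donor ", label, " has fewer than ", min_lobules,
           " lobules with islets", call. = FALSE)
    }
    fit <- lme4::lmer(pt_z ~ x + (1 | lobule_id), data = df, REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore"))
    .summarise_hlm(fit, type = "two-level", term = "x")
  }
  if (!is.null(donor)) {
    return(fit_one(df_all[df_all$donor_id == donor, ], donor))
  }
  donors <- unique(df_all$donor_id)
  fits <- lapply(donors, function(d) fit_one(df_all[df_all$donor_id == d, ], d))
  names(fits) <- donors
  out <- dplyr::bind_rows(lapply(donors, function(d) {
    t <- tidy(fits[[d]])
    t$donor_id <- d
    t
  }))
  attr(out, "fits") <- fits
  out
}

#' Three-level hierarchical model across donors
#'
#' REML fit of `pt_z ~ x + (1 + x | donor) + (1 | donor:lobule)`: donor-level
#' random intercept and slope with unstructured covariance, plus a
#' lobule-level random intercept. The fixed slope is reported with
#' Satterthwaite degrees of freedom (likelihood-ratio fallback, flagged, if
#' the Satterthwaite computation fails).
#'
#' @param ab A `lobular_abundance`.
#' @param cell_type Covariate cell type.
#' @param min_donors,min_lobules Design floors.
#' @return An `hlm_fit`.
#' @export
fit_three_level_hlm <- function(ab, cell_type, min_donors = 3,
                                min_lobules = 3) {
  df <- .hlm_frame(ab, cell_type)
  if (length(unique(df$donor_id)) < min_donors) {
    stop("need at least ", min_donors, " donors", call. = FALSE)
  }
  lob_per_donor <- tapply(df$lobule_id, df$donor_id,
                          function(x) length(unique(x)))
  if (any(lob_per_donor < min_lobules)) {
    stop("every donor needs at least ", min_lobules, " lobules with islets",
         call. = FALSE)
  }
  if (stats::sd(df$x) == 0) stop("covariate is constant; slope inestimable",
                                 call. = FALSE)
  df$lobule_uid <- paste(df$donor_id, df$lobule_id, sep = ":")
  fit <- lme4::lmer(pt_z ~ x + (1 + x | donor_id) + (1 | lobule_uid),
                    data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  .summarise_hlm(fit, type = "three-level", term = "x")
}

# shared fixed-effect summary with Satterthwaite inference
.summarise_hlm <- function(fit, type, term) {
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  rows <- lapply(names(beta), function(tm) {
    L <- as.numeric(names(beta) == tm)
    sat <- tryCatch(satterthwaite_df(fit, L), error = function(e) NULL)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tval <- beta[[tm]] / se
    if (!is.null(sat) && is.finite(sat$df) && sat$df > 0) {
      tibble::tibble(term = tm, estimate = beta[[tm]], se = se,
                     statistic = tval, df = sat$df,
                     p_value = 2 * stats::pt(-abs(tval), sat$df),
                     inference = "satterthwaite")
    } else {
      # Wald-normal fallback, reported as such
      tibble::tibble(term = tm, estimate = beta[[tm]], se = se,
                     statistic = tval, df = Inf,
                     p_value = 2 * stats::pnorm(-abs(tval)),
                     inference = "wald-normal")
    }
  })
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  lob_grp <- grep("lobule", vc$grp, value = TRUE)
  tau2 <- sum(vc$vcov[vc$grp %in% lob_grp & is.na(vc$var2) &
                        (is.na(vc$var1) | vc$var1 == "(Intercept)")])
  new_hlm_fit(type = type, model = fit, fixed = dplyr::bind_rows(rows),
              tau2 = tau2, sigma2 = sigma2,
              icc = NA_real_, n_obs = stats::nobs(fit),
              n_groups = lme4::ngrps(fit), singular = singular)
}

new_hlm_fit <- function(type, model, fixed, tau2, sigma2, icc, n_obs,
                        n_groups, singular = lme4::isSingular(model,
                                                              tol = 1e-4)) {
  structure(list(type = type, model = model, fixed = fixed, tau2 = tau2,
                 sigma2 = sigma2, icc = icc, n_obs = n_obs,
                 n_groups = n_groups, singular = singular,
                 converged = length(model@optinfo$conv$lme4) == 0),
            class = "hlm_fit")
}

#' @export
print.hlm_fit <- function(x, ...) {
  cat("<hlm_fit> ", x$type, " model, n = ", x$n_obs, "\n", sep = "")
  if (x$type == "icc") {
    cat(sprintf("  tau^2 = %.4f, sigma^2 = %.4f, ICC = %.3f\n",
                x$tau2, x$sigma2, x$icc))
  } else {
    print(as.data.frame(x$fixed), row.names = FALSE)
  }
  if (x$singular) cat("  (singular fit: variance component at boundary)\n")
  invisible(x)
}

#' Tidy the fixed effects of a hierarchical model fit
#' @param x An `hlm_fit`.
#' @param ... Unused.
#' @return Tibble of fixed-effect terms with Satterthwaite df and p-values.
#' @exportS3Method generics::tidy
tidy.hlm_fit <- function(x, ...) x$fixed

#' One-row model summary of a hierarchical model fit
#' @param x An `hlm_fit`.
#' @param ... Unused.
#' @return One-row tibble: variance components, ICC, convergence flags.
#' @exportS3Method generics::glance
glance.hlm_fit <- function(x, ...) {
  tibble::tibble(type = x$type, tau2 = x$tau2, sigma2 = x$sigma2,
                 icc = x$icc, n_obs = x$n_obs, singular = x$singular,
                 converged = x$converged)
}

#' Satterthwaite degrees of freedom for a fixed-effect contrast
#'
#' Implements the standard mixed-model Satterthwaite approximation: the REML
#' criterion is expressed as a function of the variance parameters
#' `(theta, sigma)`, the covariance of their estimates is approximated by
#' twice the inverse finite-difference Hessian, and the gradient of
#' `Var(L' beta)` with respect to the variance parameters is obtained by
#' central differences. Then `df = 2 (L' V L)^2 / (g' A g)`.
#'
#' @param fit A fitted `lmerMod` (REML).
#' @param L Numeric contrast vector over the fixed effects.
#' @return List with `df`, `var_contrast`.
#' @export
satterthwaite_df <- function(fit, L) {
  if (!lme4::isREML(fit)) stop("Satterthwaite df require a REML fit",
                               call. = FALSE)
  devfun <- stats::update(fit, devFunOnly = TRUE)
  env <- environment(devfun)
  n <- length(env$resp$y)
  reml_crit <- function(varpar) {
    p <- length(varpar)
    sigma2 <- varpar[p]^2
    theta <- varpar[-p]
    devfun(theta)
    ldL2 <- env$pp$ldL2()
    rss <- env$resp$wrss() + env$pp$sqrL(1)
    RX <- env$pp$RX()
    pfix <- ncol(RX)
    ldL2 + rss / sigma2 + n * log(2 * pi * sigma2) +
      2 * c(determinant(RX)$modulus) - pfix * log(2 * pi * sigma2)
  }
  vcov_contrast <- function(varpar) {
    p <- length(varpar)
    devfun(varpar[-p])
    unsc <- as.matrix(env$pp$unsc())
    drop(t(L) %*% (varpar[p]^2 * unsc) %*% L)
  }
  varpar <- c(lme4::getME(fit, "theta"), stats::sigma(fit))
  h <- pmax(abs(varpar), 1) * 1e-4
  H <- .fd_hessian(reml_crit, varpar, h)
  A <- tryCatch(2 * solve(H), error = function(e) NULL)
  g <- .fd_gradient(vcov_contrast, varpar, h)
  vLbL <- vcov_contrast(varpar)
  # leave the model objects at the fitted optimum
  devfun(varpar[-length(varpar)])
  if (is.null(A)) return(list(df = NA_real_, var_contrast = vLbL))
  denom <- drop(t(g) %*% A %*% g)
  if (!is.finite(denom) || denom <= 0) {
    return(list(df = NA_real_, var_contrast = vLbL))
  }
  list(df = 2 * vLbL^2 / denom, var_contrast = vLbL)
}

.fd_gradient <- function(f, x, h) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

.fd_hessian <- function(f, x, h) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) {
      for (j in (i + 1):p) {
        ej <- numeric(p); ej[j] <- h[j]
        H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                      f(x - ei + ej) + f(x - ei - ej)) / (4 * h[i] * h[j])
        H[j, i] <- H[i, j]
      }
    }
  }
  H
}
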