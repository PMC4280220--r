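## Mother-child duo multinomial risk models.
##
## A pregnancy's disease risk is baseline * mu(m, c, origin) where m and c are
## the maternal and child risk-allele dosages and `origin` records whether a
## heterozygous child's risk allele came from the mother. Under Hardy-Weinberg
## equilibrium, random mating and a rare disease, case duos follow the
## population duo distribution re-weighted by mu, and control duos follow the
## population distribution itself.

#' Duo risk-model parameters
#'
#' Bundles the allele frequency and risk multipliers of the duo multinomial
#' model. \code{R1}, \code{R2} multiply risk for a child carrying 1 or 2
#' copies of the risk allele; \code{S1}, \code{S2} for the mother; \code{Im}
#' multiplies risk when a heterozygous child's risk allele is maternally
#' derived (maternal imprinting); \code{gamma01} and \code{gamma21} are
#' maternal-fetal incompatibility interaction multipliers active when the
#' child has one copy and the mother zero or two copies respectively.
#'
#' @param q risk-allele frequency, in (0, 1).
#' @param R1,R2,S1,S2,Im,gamma01,gamma21 positive risk multipliers (default 1
#'   = no effect).
#' @return Named numeric vector of length 8.
#' @export
dyadParams <- function(q, R1 = 1, R2 = 1, S1 = 1, S2 = 1, Im = 1,
                       gamma01 = 1, gamma21 = 1) {
    p <- c(q = q, R1 = R1, R2 = R2, S1 = S1, S2 = S2, Im = Im,
           gamma01 = gamma01, gamma21 = gamma21)
    if (q <= 0 || q >= 1)
        stop("q must lie strictly in (0, 1)")
    if (any(p[-1] <= 0))
        stop("risk multipliers must be positive")
    p
}

## free multipliers per model label; q is always free
dyadModelFreeParams <- function(model) {
    switch(model,
        "Null"   = character(),
        "F"      = c("R1", "R2"),
        "M"      = c("S1", "S2"),
        "M+F"    = c("R1", "R2", "S1", "S2"),
        "I"      = c("R1", "R2", "S1", "S2", "gamma01", "gamma21"),
        "M+F+Im" = c("R1", "R2", "S1", "S2", "Im"),
        stop("unknown model label: ", model))
}

#' Analytic duo cell probabilities
#'
#' Computes case and control probabilities over the seven
#' Mendelian-compatible (mother, child) dosage cells. Control duos follow the
#' population duo distribution implied by HWE and random mating; case duos are
#' the population origin-resolved configurations re-weighted by the risk
#' multiplier \eqn{\mu(m, c, origin)} and renormalized (rare-disease
#' approximation).
#'
#' @param params parameter vector from \code{\link{dyadParams}}.
#' @return List with numeric 7-vectors \code{case} and \code{control}, named
#'   by cell \code{"m/c"}, each summing to 1.
#' @export
dyadCellProbabilities <- function(params) {
    q <- params[["q"]]
    if (q <= 0 || q >= 1) stop("degenerate allele frequency")
    p <- 1 - q
    R1 <- params[["R1"]]; R2 <- params[["R2"]]
    S1 <- params[["S1"]]; S2 <- params[["S2"]]
    Im <- params[["Im"]]
    g01 <- params[["gamma01"]]; g21 <- params[["gamma21"]]
    ## population probabilities, heterozygous-child cells split by origin
    pop <- c(p^3,                 # (0,0)
             p^2 * q,             # (0,1) paternal origin
             p^2 * q,             # (1,0)
             p^2 * q + p * q^2,   # (1,1) maternal + paternal
             p * q^2,             # (1,2)
             p * q^2,             # (2,1) maternal origin
             q^3)                 # (2,2)
    names(pop) <- DYAD_CELLS
    ## case cells: population x risk multiplier, by origin where it matters
    unnorm <- c(p^3,
                p^2 * q * R1 * g01,
                p^2 * q * S1,
                p^2 * q * S1 * R1 * Im + p * q^2 * S1 * R1,
                p * q^2 * S1 * R2,
                p * q^2 * S2 * R1 * Im * g21,
                q^3 * S2 * R2)
    list(case = setNames(unnorm / sum(unnorm), DYAD_CELLS), control = pop)
}

#' Duo multinomial log-likelihood
#'
#' @param caseCounts,controlCounts integer 7-vectors of duo counts in the
#'   standard cell order for a single variant.
#' @param params parameter vector from \code{\link{dyadParams}}.
#' @return Log-likelihood; \code{-Inf} if a positive count sits on a
#'   zero-probability cell.
#' @export
dyadLoglik <- function(caseCounts, controlCounts, params) {
    pr <- dyadCellProbabilities(params)
    ll <- 0
    for (side in c("case", "control")) {
        n <- if (side == "case") caseCounts else controlCounts
        prob <- pr[[side]]
        pos <- n > 0
        if (any(pos & prob <= 0)) return(-Inf)
        ll <- ll + sum(n[pos] * log(prob[pos]))
    }
    ll
}

## moment-style initial value: q from mothers' dosages pooled over both arms
## (controls dominate under the rare-disease model, but cases still carry
## allele-frequency information through the mother margin)
dyadInitialQ <- function(caseCounts, controlCounts) {
    m <- DYAD_CELL_M
    tot <- caseCounts + controlCounts
    q0 <- sum(tot * m) / (2 * sum(tot))
    min(max(q0, 0.02), 0.98)
}

#' Fit a duo risk model by maximum likelihood
#'
#' Maximizes the duo multinomial likelihood over the allele frequency and the
#' model's free multipliers, on unconstrained transforms (logit q, log
#' multipliers) with quasi-Newton optimization and perturbed multi-starts.
#'
#' @param caseCounts,controlCounts integer 7-vectors for one variant.
#' @param model model label: \code{"Null"}, \code{"F"}, \code{"M"},
#'   \code{"M+F"}, \code{"I"} or \code{"M+F+Im"}.
#' @param nStarts number of optimization starts (first from moment-style
#'   initials, the rest perturbed).
#' @param init optional full parameter vector used as the first start (e.g. a
#'   nested model's MLE when fitting its extension).
#' @return A \linkS4class{DyadModelFit}.
#' @export
fitDyadModel <- function(caseCounts, controlCounts, model = "M+F",
                         nStarts = 5L, init = NULL) {
    free <- dyadModelFreeParams(model)
    n <- sum(caseCounts) + sum(controlCounts)
    if (n < 20)
        stop("need at least 20 dyads to fit a duo model")
    base <- dyadParams(q = 0.5)

    toParams <- function(theta) {
        pa <- base
        pa[["q"]] <- plogis(theta[1])
        if (length(free)) pa[free] <- exp(theta[-1])
        pa
    }
    negll <- function(theta) {
        if (any(!is.finite(theta)) || abs(theta[1]) > 30 ||
            (length(theta) > 1 && any(abs(theta[-1]) > 30)))
            return(1e10)
        ll <- dyadLoglik(caseCounts, controlCounts, toParams(theta))
        if (!is.finite(ll)) 1e10 else -ll
    }

    q0 <- dyadInitialQ(caseCounts, controlCounts)
    theta0 <- c(qlogis(q0), rep(0, length(free)))
    if (!is.null(init))
        theta0 <- c(qlogis(init[["q"]]),
                    if (length(free)) log(init[free]) else numeric())
    best <- NULL
    for (s in seq_len(max(1L, nStarts))) {
        th <- if (s == 1) theta0 else
            theta0 + rnorm(length(theta0), sd = 0.5)
        fit <- tryCatch(
            optim(th, negll, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-12)),
            error = function(e) NULL)
        if (is.null(fit)) next
        if (fit$convergence != 0) {
            polish <- tryCatch(
                optim(fit$par, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12)),
                error = function(e) NULL)
            if (!is.null(polish) && polish$value <= fit$value) fit <- polish
        }
        if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
    }
    if (is.null(best))
        return(new("DyadModelFit", model = model, params = base,
                   loglik = NA_real_, k = length(free) + 1L, bic = NA_real_,
                   n = as.integer(n), converged = FALSE))
    pars <- toParams(best$par)
    ll <- -best$value
    k <- length(free) + 1L
    new("DyadModelFit", model = model, params = pars, loglik = ll, k = k,
        bic = -2 * ll + k * log(n), n = as.integer(n),
        converged = best$convergence == 0)
}

#' Likelihood ratio test between nested duo model fits
#'
#' @param fitFull,fitReduced \linkS4class{DyadModelFit} objects, the reduced
#'   model nested in the full one.
#' @param df degrees of freedom (difference in free parameters; taken from the
#'   fits when omitted).
#' @return List with \code{statistic} (2 x loglik difference, clipped at 0)
#'   and chi-square \code{p}.
#' @export
likelihoodRatioTest <- function(fitFull, fitReduced,
                                df = fitFull@k - fitReduced@k) {
    if (!fitFull@converged || !fitReduced@converged)
        stop("both fits must have converged")
    stat <- 2 * (fitFull@loglik - fitReduced@loglik)
    if (stat < -1e-6)
        stop("full model fits worse than reduced: optimization failure")
    stat <- max(stat, 0)
    list(statistic = stat, p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' BIC model selection over the duo model family
#'
#' Fits Null, F, M, M+F and I to one variant's duo counts and lays out the
#' standard comparison table (I vs M+F; M+F vs F, M, Null; M vs Null; F vs
#' Null; Null), reporting each first model's log-likelihood, the nested LRT
#' statistic and BIC. The selected model minimizes BIC over converged fits.
#'
#' @param caseCounts,controlCounts integer 7-vectors for one variant.
#' @param nStarts optimization starts per fit.
#' @return List with \code{table} (data.frame of comparison rows),
#'   \code{fits} (named list of \linkS4class{DyadModelFit}) and
#'   \code{selected} (model label).
#' @export
selectBestModel <- function(caseCounts, controlCounts, nStarts = 5L) {
    fitN <- fitDyadModel(caseCounts, controlCounts, "Null", nStarts)
    fitF <- fitDyadModel(caseCounts, controlCounts, "F", nStarts,
                         init = fitN@params)
    fitM <- fitDyadModel(caseCounts, controlCounts, "M", nStarts,
                         init = fitN@params)
    initMF <- fitM@params
    initMF[c("R1", "R2")] <- fitF@params[c("R1", "R2")]
    fitMF <- fitDyadModel(caseCounts, controlCounts, "M+F", nStarts,
                          init = initMF)
    fitI <- fitDyadModel(caseCounts, controlCounts, "I", nStarts,
                         init = fitMF@params)
    fits <- list(Null = fitN, F = fitF, M = fitM, "M+F" = fitMF, I = fitI)

    cmp <- list(c("I", "M+F"), c("M+F", "F"), c("M+F", "M"),
                c("M+F", "Null"), c("M", "Null"), c("F", "Null"),
                c("Null", NA))
    rows <- lapply(cmp, function(pair) {
        a <- fits[[pair[1]]]
        lrt <- NA_real_
        if (!is.na(pair[2]) && a@converged && fits[[pair[2]]]@converged)
            lrt <- likelihoodRatioTest(a, fits[[pair[2]]])$statistic
        data.frame(
            comparison = if (is.na(pair[2])) "Model Null" else
                paste("Model", pair[1], "vs Model", pair[2]),
            loglik = a@loglik, lrt = lrt,
            bic = a@bic, converged = a@converged,
            stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    conv <- vapply(fits, function(f) f@converged, logical(1))
    bics <- vapply(fits, function(f) f@bic, numeric(1))
    selected <- names(fits)[conv][which.min(bics[conv])]
    list(table = tab, fits = fits, selected = selected)
}

#' Per-variant maternal imprinting likelihood-ratio scan
#'
#' For each variant, fits M+F and its imprinting extension M+F+Im and reports
#' the 1-df likelihood-ratio statistic and p-value; rows with p below
#' \code{alpha} are flagged (significant parent-of-origin evidence).
#'
#' @param dyads a \linkS4class{DyadDataset}.
#' @param variants optional character vector of variant ids to scan.
#' @param nStarts optimization starts per fit (the extension is additionally
#'   started from the M+F solution, so 2 is reliable at scan scale).
#' @param alpha significance flag threshold.
#' @return data.frame with one row per analyzable variant: id, loglik of both
#'   fits, LRT statistic, p, significance flag.
#' @export
imprintingScan <- function(dyads, variants = NULL, nStarts = 2L,
                           alpha = 0.05) {
    ids <- rownames(caseCounts(dyads))
    if (!is.null(variants)) ids <- intersect(ids, variants)
    out <- lapply(ids, function(v) {
        cc <- caseCounts(dyads)[v, ]
        kc <- controlCounts(dyads)[v, ]
        ## monomorphic in the observed duos: nothing to fit
        m <- DYAD_CELL_M; ch <- DYAD_CELL_C
        tot <- cc + kc
        if (sum(tot * (m + ch)) == 0 ||
            sum(tot * (4 - m - ch)) == 0)
            return(data.frame(id = v, loglik_mf = NA, loglik_im = NA,
                              lrt = NA, p = NA, significant = NA,
                              skipped = TRUE))
        fmf <- fitDyadModel(cc, kc, "M+F", nStarts)
        fim <- fitDyadModel(cc, kc, "M+F+Im", nStarts, init = fmf@params)
        lr <- tryCatch(likelihoodRatioTest(fim, fmf, df = 1),
                       error = function(e) NULL)
        if (is.null(lr))
            return(data.frame(id = v, loglik_mf = fmf@loglik,
                              loglik_im = fim@loglik, lrt = NA, p = NA,
                              significant = NA, skipped = TRUE))
        data.frame(id = v, loglik_mf = fmf@loglik, loglik_im = fim@loglik,
                   lrt = lr$statistic, p = lr$p,
                   significant = lr$p < alpha, skipped = FALSE)
    })
    do.call(rbind, out)
}
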