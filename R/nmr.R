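## NMR chemical-shift-perturbation statistics: combined CSP, notable-residue
## classification, fast-exchange titration fitting, structure mapping with
## site enrichment, and heteronuclear NOE comparison.

#' Combined 1H/15N chemical-shift perturbation
#'
#' `sqrt((dH^2 + 0.14 * dN^2) / 2)`: the amide 15N contribution is scaled by
#' 0.14 to account for the wider 15N shift range before averaging with the
#' 1H contribution.
#'
#' @param dH,dN proton and nitrogen shift differences (ppm); vectorized.
#' @return combined perturbation (ppm, non-negative).
#' @export
combinedCSP <- function(dH, dN) {
  if (any(!is.finite(dH)) || any(!is.finite(dN)))
    stop("shift differences must be finite")
  sqrt((dH^2 + 0.14 * dN^2) / 2)
}

#' Read a Sparky-style peak list
#'
#' Whitespace-delimited rows of `assignment  dH  dN`; the assignment is a
#' residue number with an optional one- or three-letter amino-acid prefix and
#' optional atom suffix (e.g. `A45`, `LYS45`, `K45N-H`, `45`).
#'
#' @param file path to the peak list.
#' @param condition label for this condition (e.g. "apo").
#' @return data.frame with columns `assignment`, `resno`, `dH`, `dN` and a
#'   `condition` attribute.
#' @export
readPeakList <- function(file, condition = "") {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines) &
                   !grepl("^Assignment", lines, ignore.case = TRUE)]
  if (!length(lines)) stop("empty peak list: ", file)
  parts <- strsplit(lines, "\\s+")
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed peak-list line ", bad[1], ": '", lines[bad[1]], "'")
  assignment <- vapply(parts, `[[`, character(1), 1L)
  dH <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  dN <- as.numeric(vapply(parts, `[[`, character(1), 3L))
  if (anyNA(dH) || anyNA(dN)) stop("non-numeric shift in peak list: ", file)
  peakList(assignment, dH, dN, condition = condition)
}

#' Construct a peak list
#'
#' @param assignment assignment labels (residue number with optional
#'   amino-acid code and atom suffix).
#' @param dH,dN chemical shifts (ppm).
#' @param condition condition label.
#' @return data.frame peak list (see [readPeakList()]).
#' @export
peakList <- function(assignment, dH, dN, condition = "") {
  resno <- suppressWarnings(
    as.integer(sub("^[A-Za-z]{0,3}(\\d+).*$", "\\1", assignment)))
  if (anyNA(resno))
    stop("cannot parse residue number from assignment(s): ",
         paste(assignment[is.na(resno)], collapse = ", "))
  if (anyDuplicated(assignment))
    stop("duplicate assignments in peak list")
  out <- data.frame(assignment = as.character(assignment), resno = resno,
                    dH = dH, dN = dN, stringsAsFactors = FALSE)
  attr(out, "condition") <- condition
  out
}

#' Write a peak list in Sparky-like format
#'
#' @param peaks peak list data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writePeakList <- function(peaks, file) {
  writeLines(c("Assignment  w1(1H)  w2(15N)",
               sprintf("%-10s %9.4f %9.3f", peaks$assignment, peaks$dH,
                       peaks$dN)), file)
  invisible(file)
}

#' Per-residue CSP profile between two conditions
#'
#' Matches peaks by assignment label, computes the combined perturbation for
#' every shared assignment and classifies residues as notable when their
#' perturbation exceeds `max(2 * sigma, 2 * sigmaExp)`, where sigma is the
#' standard deviation of all perturbations in the comparison and sigmaExp is
#' the intrinsic experimental error (from the spectra's digital resolution).
#'
#' @param apo,holo peak lists ([peakList()] / [readPeakList()]).
#' @param sigmaExp intrinsic experimental error (ppm, default 0.01).
#' @return A [CSPProfile-class].
#' @export
cspProfile <- function(apo, holo, sigmaExp = 0.01) {
  shared <- intersect(apo$assignment, holo$assignment)
  if (length(shared) == 0) stop("no shared assignments between peak lists")
  ia <- match(shared, apo$assignment)
  ih <- match(shared, holo$assignment)
  dH <- holo$dH[ih] - apo$dH[ia]
  dN <- holo$dN[ih] - apo$dN[ia]
  delta <- combinedCSP(dH, dN)
  sigma <- stats::sd(delta)
  if (is.na(sigma)) sigma <- 0
  thr <- max(2 * sigma, 2 * sigmaExp)
  d <- data.frame(resno = apo$resno[ia], assignment = shared,
                  dH = dH, dN = dN, delta = delta, notable = delta > thr,
                  stringsAsFactors = FALSE)
  d <- d[order(d$resno), , drop = FALSE]
  rownames(d) <- NULL
  new("CSPProfile", data = d, sigma = sigma, sigmaExp = sigmaExp,
      missing = union(setdiff(apo$assignment, shared),
                      setdiff(holo$assignment, shared)),
      conditions = c(attr(apo, "condition") %||% "a",
                     attr(holo, "condition") %||% "b"))
}

`%||%` <- function(a, b) if (is.null(a) || !nzchar(a)) b else a

#' Assemble a titration series from peak lists
#'
#' @param apo reference (zero-ligand) peak list.
#' @param holoList list of peak lists, one per ligand concentration.
#' @param concentrations molar ligand concentrations (strictly increasing,
#'   aligned with `holoList`).
#' @param Ptotal molar protein concentration (default 1e-4).
#' @return A [TitrationSeries-class] over the assignments shared by all
#'   lists.
#' @export
titrationSeries <- function(apo, holoList, concentrations, Ptotal = 1e-4) {
  stopifnot(length(holoList) == length(concentrations))
  shared <- Reduce(intersect, c(list(apo$assignment),
                                lapply(holoList, `[[`, "assignment")))
  if (!length(shared)) stop("no assignments shared across the titration")
  delta <- vapply(holoList, function(h) {
    p <- cspProfile(apo, h)
    d <- cspData(p)
    d$delta[match(shared, d$assignment)]
  }, numeric(length(shared)))
  delta <- matrix(delta, nrow = length(shared))
  rownames(delta) <- as.character(apo$resno[match(shared, apo$assignment)])
  new("TitrationSeries", concentrations = concentrations, Ptotal = Ptotal,
      delta = delta)
}

## fast-exchange 1:1 bound fraction at total ligand L, total protein P
bound_fraction <- function(L, P, Kd) {
  s <- P + L + Kd
  (s - sqrt(s^2 - 4 * P * L)) / (2 * P)
}

#' Fit a 1:1 fast-exchange binding isotherm to a titration
#'
#' Under fast exchange the observed perturbation is the population-weighted
#' average, so `delta(L) = ddMax * (P + L + Kd - sqrt((P + L + Kd)^2 -
#' 4 P L)) / (2 P)`. A single global Kd is fit across the residue set
#' together with one ddMax per residue, by bounded Levenberg-Marquardt
#' least squares with three log-spaced Kd starts.
#'
#' @param series a [TitrationSeries-class].
#' @param residues residue numbers (rownames of the series) to fit; default
#'   all.
#' @param KdBounds lower/upper Kd bounds, molar.
#' @return list with `status` ("ok" or "no binding detected"), `Kd` (molar),
#'   `ddMax` (named per-residue vector, ppm), `saturated` (FALSE when the
#'   fitted Kd exceeds the highest ligand concentration), and `rss`.
#' @export
fitTitration <- function(series, residues = NULL,
                         KdBounds = c(1e-7, 1)) {
  stopifnot(is(series, "TitrationSeries"))
  D <- series@delta
  if (!is.null(residues)) {
    keep <- rownames(D) %in% as.character(residues)
    if (!any(keep)) stop("none of the requested residues are in the series")
    D <- D[keep, , drop = FALSE]
  }
  L <- series@concentrations
  if (length(L) < 3) stop("at least 3 concentrations are required")
  P <- series@Ptotal
  if (all(D == 0))
    return(list(status = "no binding detected", Kd = NA_real_,
                ddMax = setNames(rep(NA_real_, nrow(D)), rownames(D)),
                saturated = NA, rss = NA_real_))
  nr <- nrow(D)
  resid_fun <- function(par) {
    Kd <- exp(par[1])
    dd <- par[-1]
    pred <- outer(dd, bound_fraction(L, P, Kd))
    as.numeric(pred - D)
  }
  starts <- log(c(1e-5, 1e-3, 1e-1))
  best <- NULL
  for (s0 in starts) {
    dd0 <- pmax(apply(D, 1L, max), 1e-4) /
      max(bound_fraction(max(L), P, exp(s0)), 1e-6)
    fit <- try(minpack.lm::nls.lm(
      par = c(s0, dd0), fn = resid_fun,
      lower = c(log(KdBounds[1]), rep(0, nr)),
      upper = c(log(KdBounds[2]), rep(10, nr)),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(list(status = "fit did not converge", Kd = NA_real_,
                ddMax = setNames(rep(NA_real_, nr), rownames(D)),
                saturated = NA, rss = NA_real_))
  par <- best$fit$par
  Kd <- unname(exp(par[1]))
  list(status = "ok", Kd = Kd,
       ddMax = setNames(par[-1], rownames(D)),
       saturated = Kd <= max(L), rss = best$rss)
}

#' Map a CSP profile onto a structure and test site enrichment
#'
#' Writes each residue's combined perturbation into the B-factor column of
#' all its atoms (zero for residues absent from the profile), and reports
#' what fraction of notable residues lies within `siteRadius` of the target
#' site (CA-CA distance to any site residue), together with a one-sided
#' hypergeometric probability of drawing at least that many near-site
#' residues among the notables by chance.
#'
#' @param profile a [CSPProfile-class].
#' @param s a [PDBStructure-class].
#' @param site residue numbers defining the target site.
#' @param siteRadius CA-distance defining "surrounding the site" (Angstrom,
#'   default 8).
#' @param chain chain to annotate (default: first chain).
#' @return list with `structure` (annotated copy), `fraction`, `pvalue`,
#'   `classification` ("site", "off-site" or "no binding"), and the counts
#'   used (`nNotable`, `nNearSite`, `nProfile`, `nSiteLike`).
#' @export
mapToStructure <- function(profile, s, site, siteRadius = 8, chain = NULL) {
  a <- s@atoms
  if (is.null(chain)) chain <- a$chain[1]
  d <- cspData(profile)
  present <- d$resno %in% a$resno[a$chain == chain]
  if (!any(present))
    stop("no profile residue found in the structure")

  ann <- a
  ann$bfactor <- 0
  m <- match(paste(ann$chain, ann$resno), paste(chain, d$resno))
  ann$bfactor[!is.na(m)] <- d$delta[m[!is.na(m)]]
  annotated <- new("PDBStructure", atoms = ann, modelId = s@modelId)

  ca <- ca_table(s, chain)
  prof_res <- d$resno[present]
  site_ca <- ca[ca$resno %in% site, c("x", "y", "z"), drop = FALSE]
  near_site <- function(res) {
    i <- match(res, ca$resno)
    ok <- !is.na(i)
    out <- rep(NA, length(res))
    if (nrow(site_ca) == 0) { out[ok] <- FALSE; return(out) }
    dm <- cross_dist(as.matrix(ca[i[ok], c("x", "y", "z")]),
                     as.matrix(site_ca))
    out[ok] <- apply(dm, 1L, min) <= siteRadius
    out
  }
  prof_near <- near_site(prof_res)
  notable <- d$resno[present & d$notable]
  if (length(notable) == 0)
    return(list(structure = annotated, fraction = NA_real_,
                pvalue = NA_real_, classification = "no binding",
                nNotable = 0L, nNearSite = 0L,
                nProfile = length(prof_res),
                nSiteLike = sum(prof_near, na.rm = TRUE)))
  not_near <- near_site(notable)
  k <- sum(not_near, na.rm = TRUE)
  n <- length(notable)
  K <- sum(prof_near, na.rm = TRUE)
  N <- length(prof_res)
  fraction <- k / n
  ## P(X >= k), X ~ Hypergeometric(K site-like, N - K others, n draws)
  pvalue <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(structure = annotated, fraction = fraction, pvalue = pvalue,
       classification = if (fraction >= 0.5) "site" else "off-site",
       nNotable = n, nNearSite = as.integer(k), nProfile = N,
       nSiteLike = as.integer(K))
}

#' Compare two heteronuclear NOE profiles
#'
#' Per-residue difference with propagated uncertainty; the global verdict is
#' "no significant change" when no residue differs by more than three times
#' its combined uncertainty.
#'
#' @param a,b data.frames with columns `resno`, `noe`, `sigma`.
#' @return list with `table` (resno, noeA, noeB, diff, sigma, flagged) and
#'   `verdict`.
#' @export
compareHetNOE <- function(a, b) {
  shared <- intersect(a$resno, b$resno)
  if (length(shared) < 2) stop("need at least 2 shared residues")
  ia <- match(shared, a$resno); ib <- match(shared, b$resno)
  diff <- b$noe[ib] - a$noe[ia]
  sig <- sqrt(a$sigma[ia]^2 + b$sigma[ib]^2)
  flagged <- abs(diff) > 3 * sig
  list(table = data.frame(resno = shared, noeA = a$noe[ia], noeB = b$noe[ib],
                          diff = diff, sigma = sig, flagged = flagged),
       verdict = if (any(flagged)) "changed" else "no significant change")
}
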