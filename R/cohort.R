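# Longitudinal patient-panel statistics: per-timepoint nonparametric
# comparisons (Kruskal-Wallis omnibus + Dunn's pairwise post-hoc) and Fisher
# linear discriminant projection of the multi-cytokine panel.

#' Longitudinal patient series
#'
#' Per-patient longitudinal counting data: for each timepoint (days since
#' treatment start) and cytokine, replicate active-pillar counts (or derived
#' concentrations), typically 3 chips x 9 images per timepoint.  The irAE
#' (immune-related adverse event) grade and severity label are annotations
#' carried through the analysis, never predicted.
#'
#' @slot patient character identifier.
#' @slot data data.frame with columns `day`, `cytokine`, `chip`, `image`,
#'   `count`.
#' @slot grade integer irAE grade 0-4.
#' @slot label character, `"severe"` or `"mild"`.
#' @export
setClass("PatientSeries", representation(
  patient = "character", data = "data.frame", grade = "integer",
  label = "character"
), validity = function(object) {
  need <- c("day", "cytokine", "chip", "image", "count")
  if (!all(need %in% names(object@data)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (length(unique(object@data$day)) < 2)
    return("a patient series needs at least 2 timepoints")
  if (any(object@data$count < 0)) return("counts must be non-negative")
  if (!object@label %in% c("severe", "mild"))
    return("label must be 'severe' or 'mild'")
  TRUE
})

#' @param patient,data,grade,label see slot descriptions.
#' @rdname PatientSeries-class
#' @export
PatientSeries <- function(patient, data, grade = 0L, label = "mild") {
  new("PatientSeries", patient = as.character(patient), data = data,
      grade = as.integer(grade), label = label)
}

setMethod("show", "PatientSeries", function(object) {
  d <- object@data
  cat(sprintf("PatientSeries '%s' (irAE grade %d, %s): days %s, %d cytokines, %d observations\n",
              object@patient, object@grade, object@label,
              paste(sort(unique(d$day)), collapse = "/"),
              length(unique(d$cytokine)), nrow(d)))
})

#' Dunn's pairwise post-hoc test
#'
#' All pairwise mean-rank comparisons after a Kruskal-Wallis test, on the
#' joint ranking of all observations with tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups.  Two-sided p-values,
#' adjusted for multiplicity (Holm by default; Bonferroni available).
#'
#' @param x numeric observations.
#' @param g grouping vector (coerced to factor).
#' @param adjust multiplicity adjustment passed to [stats::p.adjust()].
#' @return data.frame with columns `group1`, `group2`, `z`, `p`, `p.adj`.
#' @export
dunnTest <- function(x, g, adjust = c("holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n <- table(g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  T <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(g), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    s2 <- (N * (N + 1) / 12 - T) * (1 / n[[i]] + 1 / n[[j]])
    z[k] <- if (s2 > 0) (rbar[[i]] - rbar[[j]]) / sqrt(s2) else 0
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p.adj = p.adjust(p, method = adjust),
             stringsAsFactors = FALSE)
}

#' Compare timepoints of a patient series
#'
#' For one cytokine, tests whether the replicate counts differ across
#' timepoints: Kruskal-Wallis omnibus (with tie correction, via
#' [stats::kruskal.test()]) followed by Dunn's two-sided pairwise
#' comparisons with multiplicity adjustment.  Degenerate data (all values
#' identical) return an omnibus p of 1 with a warning.
#'
#' @param series a [PatientSeries-class].
#' @param cytokine analyte to test.
#' @param adjust `"holm"` (default) or `"bonferroni"`.
#' @return list with `H`, `df`, `p.value` (omnibus) and `pairwise` (Dunn
#'   table).
#' @export
compareTimepoints <- function(series, cytokine,
                              adjust = c("holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is(series, "PatientSeries"))
  d <- series@data[series@data$cytokine == cytokine, ]
  if (nrow(d) == 0) stop("no observations for cytokine ", cytokine)
  g <- factor(d$day)
  if (any(table(g) < 3))
    stop("need at least 3 observations per timepoint")
  if (length(unique(d$count)) == 1) {
    warning("degenerate data: all values identical; omnibus p = 1")
    pw <- dunnTest(d$count, g, adjust)
    return(list(H = 0, df = nlevels(g) - 1L, p.value = 1, pairwise = pw))
  }
  kw <- kruskal.test(d$count, g)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value, pairwise = dunnTest(d$count, g, adjust))
}

#' Fisher linear discriminant projection
#'
#' Fisher LDA of per-timepoint replicate vectors: computes within-class and
#' between-class scatter matrices, solves the generalised eigenproblem
#' `Sb w = lambda Sw w`, and projects the (centred) observations on the top
#' `min(classes - 1, features)` discriminants.  When the within-class
#' scatter is singular or near-singular it is regularised by a small ridge
#' proportional to its mean diagonal.  The separation statistic is the sum
#' over retained discriminants of `(w' Sb w) / (w' Sw w)` - the ratio of
#' between- to within-class scatter along the projection.
#'
#' "Clearly separable" is operationalised against a permutation null: class
#' labels are permuted `nPermutations` times and the projection is called
#' separable when the observed separation exceeds the null's 95th
#' percentile.
#'
#' @param x numeric matrix, observations x features (1-4 features supports
#'   any sub-panel of the four cytokines).
#' @param classes class labels (timepoints), one per observation; every
#'   class needs at least 2 observations.
#' @param ridge relative ridge added to the within-class scatter when it is
#'   near-singular (default `1e-6`); set to 0 to disable.
#' @param nPermutations permutation draws for the null (default 200; 0
#'   skips the permutation test and leaves the separability flag `NA`).
#' @param seed integer seed for the permutations.
#' @return a [DiscriminantResult-class].
#' @export
ldaFitProject <- function(x, classes, ridge = 1e-6, nPermutations = 200,
                          seed = NULL) {
  x <- as.matrix(x)
  classes <- factor(classes)
  if (nrow(x) != length(classes))
    stop("classes must have one label per observation row")
  if (nlevels(classes) < 2) stop("need at least 2 classes")
  sizes <- table(classes)
  if (any(sizes < 2))
    stop("class '", names(sizes)[which(sizes < 2)[1]],
         "' has fewer than 2 observations")

  sepStat <- function(cl) {
    p <- ncol(x)
    mu <- colMeans(x)
    Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
    for (lev in levels(cl)) {
      xi <- x[cl == lev, , drop = FALSE]
      mi <- colMeans(xi)
      Sw <- Sw + crossprod(sweep(xi, 2, mi))
      Sb <- Sb + nrow(xi) * tcrossprod(mi - mu)
    }
    lam <- 0
    if (ridge > 0 && rcond(Sw) < 1e-10) {
      lam <- ridge * max(mean(diag(Sw)), 1)
      Sw <- Sw + diag(lam, p)
    }
    ev <- eigen(solve(Sw, Sb))
    ord <- order(Re(ev$values), decreasing = TRUE)
    d <- min(nlevels(cl) - 1, p)
    W <- Re(ev$vectors[, ord[seq_len(d)], drop = FALSE])
    # normalise each discriminant and recompute the scatter ratio from it
    sep <- 0
    for (k in seq_len(d)) {
      w <- W[, k]
      denom <- drop(crossprod(w, Sw %*% w))
      if (denom > 0) sep <- sep + drop(crossprod(w, Sb %*% w)) / denom
    }
    list(W = W, sep = max(sep, 0))
  }

  obs <- sepStat(classes)
  xc <- sweep(x, 2, colMeans(x))
  scores <- xc %*% obs$W
  colnames(scores) <- paste0("LD", seq_len(ncol(scores)))

  nullSep <- numeric(0); separable <- NA; pval <- NA_real_
  if (nPermutations > 0) {
    nullSep <- withSeed(seed, vapply(seq_len(nPermutations), function(i)
      sepStat(sample(classes))$sep, numeric(1)))
    separable <- obs$sep > quantile(nullSep, 0.95, names = FALSE)
    pval <- (1 + sum(nullSep >= obs$sep)) / (1 + nPermutations)
  }
  new("DiscriminantResult", scores = scores, classes = classes,
      scaling = obs$W, separation = obs$sep, nullSeparation = nullSep,
      separable = as.logical(separable), pvalue = pval)
}

#' Observation matrix of a patient series
#'
#' Builds the per-replicate cytokine matrix used for LDA: one observation
#' per chip replicate (default) or per image, features ordered by cytokine.
#' Chip-level observations sum the per-image counts of that chip.
#'
#' @param series a [PatientSeries-class].
#' @param unit `"chip"` (default) or `"image"` observation unit.
#' @param cytokines optional subset/ordering of cytokines (default: all, in
#'   first-appearance order).
#' @return list with `x` (matrix) and `classes` (factor of days).
#' @export
seriesObservations <- function(series, unit = c("chip", "image"),
                               cytokines = NULL) {
  unit <- match.arg(unit)
  d <- series@data
  if (is.null(cytokines)) cytokines <- unique(d$cytokine)
  d <- d[d$cytokine %in% cytokines, ]
  key <- if (unit == "chip") interaction(d$day, d$chip, drop = TRUE)
    else interaction(d$day, d$chip, d$image, drop = TRUE)
  agg <- aggregate(count ~ day + cytokine + key, data = cbind(d, key = key),
                   FUN = sum)
  days <- tapply(agg$day, agg$key, function(v) v[1])
  x <- sapply(cytokines, function(cy) {
    v <- agg[agg$cytokine == cy, ]
    v$count[match(names(days), v$key)]
  })
  x <- matrix(as.numeric(x), ncol = length(cytokines),
              dimnames = list(NULL, cytokines))
  list(x = x, classes = factor(unname(days)))
}

#' Per-timepoint trajectory report
#'
#' Summarises each cytokine at each timepoint by interpolated median and
#' interquartile range, and flags a timepoint as *elevated* when its
#' Dunn-adjusted comparison against the earliest timepoint is significant at
#' `alpha` and its median is higher.
#'
#' @param series a [PatientSeries-class].
#' @param alpha significance level for the elevation flag (default 0.05).
#' @param adjust multiplicity adjustment for the Dunn comparisons.
#' @return data.frame with columns `cytokine`, `day`, `q1`, `median`, `q3`,
#'   `elevated`.
#' @export
trajectoryReport <- function(series, alpha = 0.05,
                             adjust = c("holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is(series, "PatientSeries"))
  d <- series@data
  days <- sort(unique(d$day))
  first <- days[1]
  out <- list()
  for (cy in unique(d$cytokine)) {
    cmp <- suppressWarnings(compareTimepoints(series, cy, adjust))
    meds <- tapply(d$count[d$cytokine == cy], d$day[d$cytokine == cy],
                   function(v) quartiles(v))
    for (day in days) {
      q <- meds[[as.character(day)]]
      elevated <- FALSE
      if (day != first) {
        pw <- cmp$pairwise
        row <- pw[(pw$group1 == as.character(first) &
                     pw$group2 == as.character(day)) |
                    (pw$group2 == as.character(first) &
                       pw$group1 == as.character(day)), ]
        elevated <- nrow(row) > 0 && row$p.adj[1] < alpha &&
          q["median"] > meds[[as.character(first)]]["median"]
      }
      out[[length(out) + 1]] <- data.frame(
        cytokine = cy, day = day, q1 = unname(q["q1"]),
        median = unname(q["median"]), q3 = unname(q["q3"]),
        elevated = elevated, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
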