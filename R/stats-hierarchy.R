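#' Region atlas along the cortical functional hierarchy
#'
#' Five regions ordered along the visual processing pathway: MT, LIP, LPFC,
#' OFC, ACC. Each region is a point cloud of surface coordinates (mm) in a
#' common reference space.
#'
#' @param points data.frame with columns `region`, `x`, `y`, `z`.
#' @param order region order used for hierarchy ranks and tie-breaking.
#' @export
region_atlas <- function(points,
                         order = c("MT", "LIP", "LPFC", "OFC", "ACC")) {
  stopifnot(all(c("region", "x", "y", "z") %in% names(points)))
  if (nrow(points) == 0) stop("empty atlas", call. = FALSE)
  if (!all(points$region %in% order))
    stop("atlas contains regions outside the declared order", call. = FALSE)
  structure(list(points = points, order = order), class = "region_atlas")
}

#' Assign electrodes to hierarchy regions
#'
#' Each electrode is labelled with the region containing its nearest atlas
#' point, provided that distance is at most `radius` (9.5 mm); otherwise it
#' is unassigned (NA). Exact distance ties are broken by the atlas region
#' order.
#'
#' @param electrodes electrode table with `x`, `y`, `z` (mm).
#' @param atlas a [region_atlas()].
#' @param radius assignment radius in mm (default 9.5).
#' @return factor of region labels (levels = atlas order), NA = unassigned;
#'   attribute `"distance"` holds the distance to the nearest atlas point.
#' @export
assign_regions <- function(electrodes, atlas, radius = 9.5) {
  stopifnot(inherits(atlas, "region_atlas"))
  pts <- atlas$points
  ecoord <- as.matrix(electrodes[, c("x", "y", "z")])
  acoord <- as.matrix(pts[, c("x", "y", "z")])
  labels <- rep(NA_character_, nrow(ecoord))
  dists <- rep(NA_real_, nrow(ecoord))
  rk <- match(pts$region, atlas$order)
  for (i in seq_len(nrow(ecoord))) {
    d <- sqrt(colSums((t(acoord) - ecoord[i, ])^2))
    dmin <- min(d)
    dists[i] <- dmin
    if (dmin <= radius) {
      cand <- which(d == dmin)
      labels[i] <- pts$region[cand[which.min(rk[cand])]]
    }
  }
  structure(factor(labels, levels = atlas$order), distance = dists)
}

#' Balance two groups by undersampling the majority
#'
#' @param group_a,group_b numeric vectors.
#' @param seed integer seed for the subsample.
#' @return list with `a` and `b`, both of minority size; the minority group
#'   is returned unchanged.
#' @export
balance_undersample <- function(group_a, group_b, seed = 1) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  m <- min(length(group_a), length(group_b))
  with_seed(seed, list(
    a = if (length(group_a) > m) group_a[sample.int(length(group_a), m)]
        else group_a,
    b = if (length(group_b) > m) group_b[sample.int(length(group_b), m)]
        else group_b))
}

#' Paired Wilcoxon signed-rank comparison with bootstrap CI
#'
#' Two-sided signed-rank test on paired per-unit values plus a seeded
#' percentile bootstrap (10^4 resamples) confidence interval of the median
#' difference.
#'
#' @param x,y paired numeric vectors (e.g. per-patient medians under two
#'   conditions).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list of class `paired_result`: `statistic`, `p_value`,
#'   `median_diff`, `ci`, `n`, `degenerate` (TRUE when all differences are
#'   zero).
#' @export
paired_wilcoxon <- function(x, y, n_boot = 1e4, seed = 1, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 complete pairs", call. = FALSE)
  d <- x - y
  degenerate <- all(d == 0)
  wt <- if (degenerate) list(statistic = c(V = 0), p.value = NA_real_)
        else suppressWarnings(wilcox.test(x, y, paired = TRUE))
  ci <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b)
      median(d[sample.int(length(d), replace = TRUE)]), numeric(1))
    quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 median_diff = median(d), ci = ci, n = length(d),
                 degenerate = degenerate),
            class = "paired_result")
}

#' Combine independent p-values with Fisher's method
#'
#' chi-squared = -2 sum log p with 2k degrees of freedom; for a single p
#' the combined value equals that p.
#'
#' @param p vector of p-values (NAs dropped).
#' @return list: `chisq`, `df`, `p`.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  p <- pmax(p, .Machine$double.xmin)
  chisq <- -2 * sum(log(p))
  df <- 2 * length(p)
  list(chisq = chisq, df = df,
       p = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_)
}

#' Per-unit TC-SC co-variation with Fisher-combined significance
#'
#' Spearman rank correlation of time-aligned (TC, SC) segment pairs within
#' each unit (patient / synthetic subject), combined across units with
#' Fisher's method (chi-squared = -2 sum log p, df = 2k). A descriptive
#' logarithmic fit `tc ~ a + b * log(sc - c)` is also reported.
#'
#' @param tc,sc paired segment values.
#' @param unit unit id per segment (single unit assumed when NULL).
#' @param min_pairs minimum complete pairs per unit (default 10).
#' @return list of class `covariation`: `per_unit` (unit, n, rho, p),
#'   `mean_rho`, `chisq`, `df`, `p_combined`, `log_fit` (coefficients or
#'   NULL).
#' @export
covariation <- function(tc, sc, unit = NULL, min_pairs = 10) {
  if (is.null(unit)) unit <- rep(1L, length(tc))
  ok <- !is.na(tc) & !is.na(sc)
  df_all <- data.frame(tc = tc[ok], sc = sc[ok], unit = unit[ok])
  per <- lapply(split(df_all, df_all$unit), function(d) {
    if (nrow(d) < min_pairs || var(d$tc) == 0 || var(d$sc) == 0)
      return(data.frame(unit = d$unit[1], n = nrow(d), rho = NA_real_,
                        p = NA_real_))
    ct <- suppressWarnings(cor.test(d$tc, d$sc, method = "spearman"))
    data.frame(unit = d$unit[1], n = nrow(d), rho = unname(ct$estimate),
               p = ct$p.value)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  fc <- fisher_combine(per$p)
  fit <- tryCatch({
    c0 <- min(df_all$sc) - 0.1 * max(sd(df_all$sc), 1e-3)
    m <- suppressWarnings(
      nls(tc ~ a + b * log(sc - cc), data = df_all,
          start = list(a = mean(df_all$tc), b = 1, cc = c0),
          control = list(warnOnly = TRUE)))
    coef(m)
  }, error = function(e) NULL)
  structure(list(per_unit = per, mean_rho = mean(per$rho, na.rm = TRUE),
                 chisq = fc$chisq, df = fc$df, p_combined = fc$p,
                 log_fit = fit),
            class = "covariation")
}

#' Hierarchy slope of temporal correlations
#'
#' Ordinary least-squares slope of per-region TC against hierarchy rank
#' (MT = 1 ... ACC = 5) within each unit, and a group-level Wilcoxon
#' signed-rank test of the slopes against zero. Units with fewer than two
#' regions are skipped and logged.
#'
#' @param data data.frame with columns `unit`, `region`, `tc`.
#' @param order hierarchy region order.
#' @return list of class `hierarchy_slope`: `slopes` (unit, slope, n),
#'   `mean_slope`, `sd_slope`, `p_value`, `skipped`.
#' @export
hierarchy_slope <- function(data,
                            order = c("MT", "LIP", "LPFC", "OFC", "ACC")) {
  stopifnot(all(c("unit", "region", "tc") %in% names(data)))
  data$rank <- match(as.character(data$region), order)
  if (anyNA(data$rank)) stop("unknown region in data", call. = FALSE)
  skipped <- character(0)
  rows <- lapply(split(data, data$unit), function(d) {
    if (length(unique(d$rank)) < 2) {
      skipped <<- c(skipped, as.character(d$unit[1]))
      return(NULL)
    }
    sl <- unname(coef(lm(tc ~ rank, data = d))[2])
    data.frame(unit = d$unit[1], slope = sl, n = nrow(d))
  })
  slopes <- do.call(rbind, rows)
  rownames(slopes) <- NULL
  p <- if (!is.null(slopes) && nrow(slopes) >= 5)
    suppressWarnings(wilcox.test(slopes$slope, mu = 0)$p.value)
  else NA_real_
  structure(list(slopes = slopes,
                 mean_slope = mean(slopes$slope),
                 sd_slope = sd(slopes$slope),
                 p_value = p, skipped = skipped),
            class = "hierarchy_slope")
}

#' Daily antiepileptic drug load
#'
#' Sum of prescribed doses normalised by each drug's defined daily dose
#' (DDD), per day, with a high/low label relative to the median day.
#'
#' @param doses data.frame with columns `date`, `drug`, `dose`.
#' @param ddd named vector of defined daily doses per drug.
#' @return data.frame: `date`, `load`, `label` ("high"/"low").
#' @export
aed_load <- function(doses, ddd) {
  stopifnot(all(c("date", "drug", "dose") %in% names(doses)))
  if (!all(doses$drug %in% names(ddd)))
    stop("missing defined daily dose for some drug", call. = FALSE)
  load <- tapply(doses$dose / ddd[doses$drug], doses$date, sum)
  out <- data.frame(date = names(load), load = as.numeric(load))
  out$label <- ifelse(out$load > median(out$load), "high", "low")
  rownames(out) <- NULL
  out
}
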