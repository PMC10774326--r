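# Nesting suitability
#
# Cluster-level nesting statistics, Spearman correlation of cluster medians
# with nesting occupancy, observed / potentially suitable / unsuitable
# classification, regional summary statistics (P_O, P_S), and pairwise
# two-sample Kolmogorov-Smirnov comparisons with Benjamini-Hochberg
# adjustment.

#' Per-cluster nesting statistics
#'
#' For each SOM cluster: member count, nesting count, percentage of nesting
#' Coastgons, and the median of each selected indicator over members. Empty
#' clusters are flagged and carry NA statistics.
#'
#' @param assignment An [assign_clusters()] result over the table's rows.
#' @param table Indicator table (rows aligned with the assignment).
#' @param species Species code (uses the `nesting_<species>` column).
#' @param indicators Indicator columns to summarize.
#' @return A `cluster_stats` data frame: `cluster`, `n`, `n_nesting`,
#'   `pct_nesting`, `empty`, and `med_<indicator>` columns.
#' @export
cluster_stats <- function(assignment, table, species,
                          indicators = attr(assignment, "indicators")) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (length(assignment$cluster) != nrow(table)) {
    stop("assignment and table are not aligned: row counts differ")
  }
  col <- paste0("nesting_", species)
  if (!col %in% names(table)) {
    stop(sprintf("no nesting flags for species '%s'", species))
  }
  k <- length(assignment$members)
  out <- data.frame(cluster = seq_len(k), n = 0L, n_nesting = 0L,
                    pct_nesting = NA_real_, empty = TRUE)
  for (ind in indicators) out[[paste0("med_", ind)]] <- NA_real_
  for (j in seq_len(k)) {
    m <- assignment$members[[j]]
    out$n[j] <- length(m)
    if (length(m) == 0) next
    out$empty[j] <- FALSE
    out$n_nesting[j] <- sum(table[[col]][m])
    out$pct_nesting[j] <- 100 * out$n_nesting[j] / out$n[j]
    for (ind in indicators) {
      out[[paste0("med_", ind)]][j] <- series_stats(table[[ind]][m], "median")
    }
  }
  structure(out, class = c("cluster_stats", "data.frame"),
            indicators = indicators, species = species)
}

#' Spearman rank correlation (average ranks for ties)
#'
#' @param x,y Numeric vectors of equal length (>= 3 after dropping pairs
#'   with missing values).
#' @return Spearman's rho in \[-1, 1\]; NaN with a warning for constant
#'   input.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant input; Spearman's rho undefined")
    return(NaN)
  }
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Correlate cluster indicator medians with nesting occupancy
#'
#' Per indicator, Spearman's rho between the cluster medians and the
#' percentage of nesting Coastgons, over non-empty clusters; |rho| < 0.1 is
#' categorized insignificant, \[0.1, 0.3) weak, >= 0.3 significant. Also
#' reports P_n, the percentage of non-empty clusters containing any nesting
#' Coastgon.
#'
#' @param stats A [cluster_stats()] result.
#' @return A `correlation_result`: data frame (`indicator`, `rho`,
#'   `category`) with attribute `P_n`.
#' @export
correlate_clusters <- function(stats) {
  stopifnot(inherits(stats, "cluster_stats"))
  ne <- stats[!stats$empty, , drop = FALSE]
  if (nrow(ne) < 3) stop("fewer than 3 non-empty clusters")
  indicators <- attr(stats, "indicators")
  rho <- vapply(indicators, function(ind) {
    spearman_rho(ne[[paste0("med_", ind)]], ne$pct_nesting)
  }, numeric(1))
  category <- ifelse(!is.finite(rho), NA_character_,
                     ifelse(abs(rho) < 0.1, "insignificant",
                            ifelse(abs(rho) < 0.3, "weak", "significant")))
  out <- data.frame(indicator = indicators, rho = unname(rho),
                    category = category, row.names = NULL)
  structure(out, class = c("correlation_result", "data.frame"),
            P_n = 100 * mean(ne$n_nesting > 0), species = attr(stats, "species"))
}

#' Classify Coastgons as observed / potentially suitable / unsuitable
#'
#' `O` for Coastgons with observed nesting; `S` for non-nesting members of
#' clusters whose percentage of nesting Coastgons meets the threshold
#' (inclusive); `U` otherwise. Rows not covered by the assignment
#' (unclustered, e.g. missing indicator values) are `U` with the
#' `unclustered` flag set.
#'
#' @param assignment An [assign_clusters()] result over the table's rows,
#'   or `NULL` entries allowed via `clustered_rows`.
#' @param table Indicator table with nesting flags (all rows).
#' @param species Species code.
#' @param threshold_pct Cluster nesting percentage making its non-nesting
#'   members potentially suitable (default 10, inclusive).
#' @param clustered_rows Optional integer vector mapping assignment rows to
#'   table rows (default: all table rows, in order).
#' @return A `suitability_map` data frame: `cell`, `species`, `category`
#'   (factor O/S/U), `unclustered`.
#' @export
classify_suitability <- function(assignment, table, species,
                                 threshold_pct = 10,
                                 clustered_rows = seq_len(nrow(table))) {
  col <- paste0("nesting_", species)
  stopifnot(col %in% names(table))
  sub <- table[clustered_rows, , drop = FALSE]
  cs <- cluster_stats(assignment, sub, species,
                      indicators = character(0))
  suitable_cluster <- !cs$empty & cs$pct_nesting >= threshold_pct
  category <- rep("U", nrow(table))
  unclustered <- rep(TRUE, nrow(table))
  unclustered[clustered_rows] <- FALSE
  cl <- assignment$cluster
  s_rows <- clustered_rows[suitable_cluster[cl]]
  category[s_rows] <- "S"
  category[table[[col]] == 1] <- "O"
  out <- data.frame(cell = table$cell, species = species,
                    category = factor(category, levels = c("O", "S", "U")),
                    unclustered = unclustered, stringsAsFactors = FALSE)
  structure(out, class = c("suitability_map", "data.frame"),
            threshold_pct = threshold_pct)
}

point_in_polygon <- function(lon, lat, polygon) {
  closed <- rbind(polygon, polygon[1, , drop = FALSE])
  mgcv::in.out(closed, cbind(lon, lat))
}

#' Regional summary statistics P_O and P_S
#'
#' Assigns each Coastgon to at most one region by point-in-polygon of its
#' CLC (overlapping regions are an error), plus a "Global" region holding
#' all Coastgons, and computes per region and species: `P_O`, the
#' percentage of observed-nesting Coastgons, and `P_S`, the percentage of
#' observed-nesting or potentially suitable Coastgons. Species with no
#' observed nesting in a region get NA (they carry no information about
#' that region and are excluded from cross-species means).
#'
#' @param maps A [classify_suitability()] result or a list of them (one per
#'   species).
#' @param grid The [build_grid()] result (for CLC positions).
#' @param regions Named list of polygon matrices (`lon`, `lat`), or `NULL`
#'   for the global summary only.
#' @return A `region_summary` data frame: `region`, `species`, `n`, `n_O`,
#'   `n_S`, `P_O`, `P_S` (percent, unrounded).
#' @export
summarize_regions <- function(maps, grid, regions = NULL) {
  if (inherits(maps, "suitability_map")) maps <- list(maps)
  cells <- grid$cells
  region_of <- rep(NA_character_, nrow(cells))
  if (!is.null(regions)) {
    hits <- matrix(FALSE, nrow(cells), length(regions))
    for (r in seq_along(regions)) {
      hits[, r] <- point_in_polygon(cells$clc_lon, cells$clc_lat,
                                    regions[[r]])
    }
    multi <- rowSums(hits) > 1
    if (any(multi)) {
      off <- apply(hits[multi, , drop = FALSE], 1, function(h) {
        paste(names(regions)[h], collapse = "+")
      })
      stop(sprintf("overlapping region polygons: %s",
                   paste(unique(off), collapse = "; ")))
    }
    for (r in seq_along(regions)) {
      region_of[hits[, r]] <- names(regions)[r]
    }
  }
  region_names <- c(names(regions), "Global")
  rows <- list()
  for (m in maps) {
    stopifnot(inherits(m, "suitability_map"))
    idx <- match(m$cell, cells$cell)
    for (rn in region_names) {
      in_region <- if (rn == "Global") rep(TRUE, nrow(m)) else {
        !is.na(region_of[idx]) & region_of[idx] == rn
      }
      n <- sum(in_region)
      if (n == 0) next
      n_O <- sum(m$category[in_region] == "O")
      n_S <- sum(m$category[in_region] == "S")
      po <- if (n_O == 0) NA_real_ else 100 * n_O / n
      ps <- if (n_O == 0) NA_real_ else 100 * (n_O + n_S) / n
      rows[[length(rows) + 1]] <- data.frame(
        region = rn, species = m$species[1], n = n, n_O = n_O, n_S = n_S,
        P_O = po, P_S = ps, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("region_summary", "data.frame"))
}

#' P_O and P_S from category counts
#'
#' Pure arithmetic used by [summarize_regions()]:
#' `P_O = 100 n_O / (n_O + n_S + n_U)` and
#' `P_S = 100 (n_O + n_S) / (n_O + n_S + n_U)`.
#'
#' @param n_O,n_S,n_U Counts of observed, potentially suitable, and
#'   unsuitable Coastgons.
#' @return Named numeric vector `P_O`, `P_S` (percent, unrounded).
#' @export
region_summary_from_counts <- function(n_O, n_S, n_U) {
  n <- n_O + n_S + n_U
  stopifnot(n > 0)
  c(P_O = 100 * n_O / n, P_S = 100 * (n_O + n_S) / n)
}

#' Cross-species means of regional percentages
#'
#' Per region, the mean of `P_O` and of `P_S` over the species with data
#' (non-NA) in that region, plus the ratio of the global mean `P_S` to the
#' global mean `P_O` when a "Global" region is present.
#'
#' @param summary A [summarize_regions()] result, or any data frame with
#'   columns `region`, `species`, `P_O`, `P_S`.
#' @return Data frame `region`, `n_species`, `mean_P_O`, `mean_P_S`, with
#'   attribute `ps_po_ratio` (global mean P_S / global mean P_O, or NA).
#' @export
cross_species_means <- function(summary) {
  stopifnot(all(c("region", "species", "P_O", "P_S") %in% names(summary)))
  regions <- unique(summary$region)
  rows <- lapply(regions, function(rn) {
    s <- summary[summary$region == rn & is.finite(summary$P_O), , drop = FALSE]
    data.frame(region = rn, n_species = nrow(s),
               mean_P_O = mean(s$P_O), mean_P_S = mean(s$P_S))
  })
  out <- do.call(rbind, rows)
  ratio <- NA_real_
  g <- out[out$region == "Global", , drop = FALSE]
  if (nrow(g) == 1 && is.finite(g$mean_P_O) && g$mean_P_O > 0) {
    ratio <- g$mean_P_S / g$mean_P_O
  }
  structure(out, ps_po_ratio = ratio)
}

#' Pairwise Kolmogorov-Smirnov comparison of suitability categories
#'
#' For each indicator and each category pair (O|S, O|U, S|U), the
#' two-sample KS statistic and p-value, with the three p-values of each
#' indicator adjusted by the Benjamini-Hochberg step-up procedure. Exact
#' p-values are used when the smaller sample has <= 25 members, asymptotic
#' otherwise. Pairs where a category has fewer than 2 members are skipped
#' with a warning.
#'
#' @param map A [classify_suitability()] result.
#' @param table Indicator table aligned with the map rows by `cell`.
#' @param indicators Indicator columns to compare.
#' @param alpha Significance level on the adjusted p-values.
#' @return A `ks_report` data frame: `indicator`, `pair`, `n1`, `n2`, `D`,
#'   `p`, `p_adj`, `significant`.
#' @export
ks_compare <- function(map, table, indicators, alpha = 0.05) {
  stopifnot(inherits(map, "suitability_map"))
  idx <- match(map$cell, table$cell)
  pairs <- list(c("O", "S"), c("O", "U"), c("S", "U"))
  rows <- list()
  for (ind in indicators) {
    vals <- table[[ind]][idx]
    prows <- list()
    for (pr in pairs) {
      x <- vals[map$category == pr[1] & is.finite(vals)]
      y <- vals[map$category == pr[2] & is.finite(vals)]
      if (length(x) < 2 || length(y) < 2) {
        warning(sprintf("skipping %s|%s for %s: a category has < 2 members",
                        pr[1], pr[2], ind))
        next
      }
      exact <- min(length(x), length(y)) <= 25
      kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
      prows[[length(prows) + 1]] <- data.frame(
        indicator = ind, pair = paste(pr, collapse = "|"),
        n1 = length(x), n2 = length(y),
        D = unname(kt$statistic), p = kt$p.value, stringsAsFactors = FALSE)
    }
    if (length(prows) == 0) next
    pdf <- do.call(rbind, prows)
    pdf$p_adj <- stats::p.adjust(pdf$p, method = "BH")
    rows[[length(rows) + 1]] <- pdf
  }
  if (length(rows) == 0) {
    out <- data.frame(indicator = character(0), pair = character(0),
                      n1 = integer(0), n2 = integer(0), D = numeric(0),
                      p = numeric(0), p_adj = numeric(0))
  } else {
    out <- do.call(rbind, rows)
  }
  out$significant <- out$p_adj < alpha
  structure(out, class = c("ks_report", "data.frame"), alpha = alpha)
}
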