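#' ORN-by-PN connectivity table
#'
#' The synapse-count adjacency matrix between all ORN axons and all PN
#' dendrites of a glomerulus pair, with left/right side labels. A connection
#' is a cell with a positive count; unilateral ORNs have zero counts toward
#' the side opposite their cell body.
#'
#' @param counts Integer matrix, ORNs in rows, PNs in columns, with row and
#'   column names.
#' @param orn_side,pn_side Character vectors of `"L"`/`"R"` labels. If
#'   omitted, parsed from the row/column names (expects ids containing
#'   `_L_`/`_R_`).
#' @param orn_bilateral Logical flags; default: an ORN is bilateral when it
#'   has a positive count on its non-home side.
#' @return A `connectivity_table` object.
#' @export
connectivity_table <- function(counts, orn_side = NULL, pn_side = NULL,
                               orn_bilateral = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("ORN_", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("PN_", seq_len(ncol(counts)))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("counts must be non-negative integers; offending cell: row ",
                 bad[1, 1], " (", rownames(counts)[bad[1, 1]], "), column ",
                 bad[1, 2], " (", colnames(counts)[bad[1, 2]], ")"))
  }
  storage.mode(counts) <- "integer"
  side_from_id <- function(ids) {
    s <- dplyr::case_when(grepl("_L(_|$)", ids) ~ "L",
                          grepl("_R(_|$)", ids) ~ "R",
                          TRUE ~ NA_character_)
    if (anyNA(s)) abort("cannot parse side labels from ids; pass them explicitly")
    s
  }
  orn_side <- orn_side %||% side_from_id(rownames(counts))
  pn_side <- pn_side %||% side_from_id(colnames(counts))
  if (length(orn_side) != nrow(counts) || length(pn_side) != ncol(counts)) {
    abort("side label lengths must match matrix dimensions")
  }
  if (is.null(orn_bilateral)) {
    # an ORN is unilateral only if contralateral PNs exist and it reaches
    # none of them
    contra <- outer(orn_side, pn_side, "!=")
    orn_bilateral <- rowSums(contra) == 0 | rowSums(counts * contra) > 0
  }
  structure(list(counts = counts, orn_side = orn_side, pn_side = pn_side,
                 orn_bilateral = orn_bilateral),
            class = "connectivity_table")
}

#' @exportS3Method base::print
print.connectivity_table <- function(x, ...) {
  cat("<connectivity_table> ", nrow(x$counts), " ORNs (",
      sum(x$orn_side == "L"), "L/", sum(x$orn_side == "R"), "R) x ",
      ncol(x$counts), " PNs (", sum(x$pn_side == "L"), "L/",
      sum(x$pn_side == "R"), "R), ", sum(x$counts > 0), " connections, ",
      sum(x$counts), " synapses\n", sep = "")
  invisible(x)
}

#' @export
tidy.connectivity_table <- function(x, ...) {
  long <- tibble::as_tibble(as.table(x$counts), .name_repair = "minimal")
  names(long) <- c("orn_id", "pn_id", "count")
  long$orn_side <- x$orn_side[match(long$orn_id, rownames(x$counts))]
  long$pn_side <- x$pn_side[match(long$pn_id, colnames(x$counts))]
  long$ipsilateral <- long$orn_side == long$pn_side
  dplyr::filter(long, .data$count > 0)
}

#' Read / write a connectivity matrix CSV
#'
#' Layout of the supplementary adjacency matrix: rows are ORNs sorted by
#' side, columns are PNs sorted by side, integer cells, first column holds the
#' ORN ids, header holds the PN ids. Sides are parsed from the ids unless
#' given.
#'
#' @param path CSV file path.
#' @inheritParams connectivity_table
#' @return `load_connectivity()` returns a [connectivity_table()];
#'   `write_connectivity()` returns `path` invisibly.
#' @export
load_connectivity <- function(path, orn_side = NULL, pn_side = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1])
  if (!is.numeric(m)) abort("connectivity cells must be numeric")
  rownames(m) <- ids
  connectivity_table(m, orn_side = orn_side, pn_side = pn_side)
}

#' @rdname load_connectivity
#' @param table A [connectivity_table()].
#' @export
write_connectivity <- function(table, path) {
  df <- tibble::as_tibble(table$counts, rownames = "orn_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' Summary statistics of the connectivity matrix
#'
#' A connection is any (ORN, PN) pair with at least one synapse. Means and
#' medians are over connected pairs, with per-connection-type
#' (ipsi/contralateral) breakdowns.
#'
#' @param table A [connectivity_table()].
#' @return One-row tibble: `n_orns`, `n_pns`, `n_connections`,
#'   `total_synapses`, `mean_synapses`, `median_synapses`, plus ipsi/contra
#'   means.
#' @export
connection_stats <- function(table) {
  long <- tidy(table)
  tibble::tibble(
    n_orns = nrow(table$counts),
    n_pns = ncol(table$counts),
    n_connections = nrow(long),
    total_synapses = sum(long$count),
    mean_synapses = mean(long$count),
    median_synapses = median(long$count),
    n_ipsi = sum(long$ipsilateral),
    n_contra = sum(!long$ipsilateral),
    mean_synapses_ipsi = mean(long$count[long$ipsilateral]),
    mean_synapses_contra = mean(long$count[!long$ipsilateral])
  )
}

#' Normalized ORN contributions to each PN's synapse pool
#'
#' Divides each connection's synapse count by the PN's total from the chosen
#' pool of ORNs, times 100. With `pool = "ipsilateral"` the pool is the PN's
#' ipsilateral ORNs (percent contribution to the ipsilateral pool); with
#' `pool = "per_antenna"` each antenna is normalized separately (percent of
#' that antenna's total onto the PN), controlling for both left-right and
#' ipsi-contra differences. Contributions sum to 100 within each (PN, pool).
#'
#' @param table A [connectivity_table()].
#' @param pool `"ipsilateral"` or `"per_antenna"`.
#' @return Tibble: `orn_id`, `pn_id`, `antenna`, `count`, `pct`.
#' @export
normalized_contributions <- function(table, pool = c("ipsilateral",
                                                     "per_antenna")) {
  pool <- match.arg(pool)
  long <- tidy(table)
  if (pool == "ipsilateral") long <- dplyr::filter(long, .data$ipsilateral)
  long <- dplyr::group_by(long, .data$pn_id, antenna = .data$orn_side)
  if (pool == "ipsilateral") {
    long <- dplyr::group_by(long, .data$pn_id)
  }
  out <- dplyr::mutate(long, pct = 100 * .data$count / sum(.data$count))
  zero <- dplyr::summarise(long, tot = sum(.data$count), .groups = "drop")
  if (any(zero$tot == 0)) abort("a normalization pool has zero synapses")
  dplyr::select(dplyr::ungroup(out), "orn_id", "pn_id", "antenna",
                "count", "pct")
}

#' Coefficient of variation of normalized ipsilateral contributions
#'
#' The connection-noise summary: sample SD over mean of the percentage
#' contributions of each ORN to its PN's ipsilateral synapse pool, pooled
#' across PNs.
#'
#' @param table A [connectivity_table()].
#' @return A single CV (dimensionless).
#' @export
contribution_cv <- function(table) {
  pct <- normalized_contributions(table, "ipsilateral")$pct
  if (length(pct) < 2) abort("need at least 2 ipsilateral connections")
  if (mean(pct) == 0) abort("mean contribution is zero")
  sd(pct) / mean(pct)
}

#' Ipsilateral versus contralateral synapse counts
#'
#' Per-PN mean synapses per connection from ipsilateral and contralateral
#' ORNs, and the pooled percent surplus `100 * (ipsi/contra - 1)` computed
#' two ways: from the grand means over connections and from the average of
#' per-PN means.
#'
#' @param table A [connectivity_table()].
#' @return List with `per_pn` (tibble: `pn_id`, `mean_ipsi`, `mean_contra`)
#'   and scalars `surplus_pct_grand`, `surplus_pct_per_pn`,
#'   `paired_t_p` (paired t-test across PNs).
#' @export
ipsi_contra_comparison <- function(table) {
  long <- tidy(table)
  per_pn <- dplyr::summarise(
    dplyr::group_by(long, .data$pn_id),
    mean_ipsi = mean(.data$count[.data$ipsilateral]),
    mean_contra = mean(.data$count[!.data$ipsilateral]),
    .groups = "drop"
  )
  grand_ipsi <- mean(long$count[long$ipsilateral])
  grand_contra <- mean(long$count[!long$ipsilateral])
  p <- tryCatch(
    stats::t.test(per_pn$mean_ipsi, per_pn$mean_contra,
                  paired = TRUE)$p.value,
    error = function(e) NA_real_)
  list(
    per_pn = per_pn,
    surplus_pct_grand = 100 * (grand_ipsi / grand_contra - 1),
    surplus_pct_per_pn = 100 * (mean(per_pn$mean_ipsi) /
                                mean(per_pn$mean_contra) - 1),
    paired_t_p = p
  )
}

#' Per-PN ORN-synapse totals and the left-right difference
#'
#' Total ORN synapses received by each PN, side means, and the percent
#' difference of the right-side mean relative to the left. When total
#' dendritic path lengths are supplied, per-micrometre synapse densities are
#' added.
#'
#' @param table A [connectivity_table()].
#' @param path_lengths Optional named numeric vector of dendritic path
#'   lengths (um) per PN id.
#' @return List with `per_pn` tibble (`pn_id`, `side`, `total_synapses`, and
#'   `density_per_um` when lengths are given) and scalar
#'   `right_vs_left_pct` = 100 * (right mean / left mean - 1).
#' @export
left_right_totals <- function(table, path_lengths = NULL) {
  totals <- colSums(table$counts)
  per_pn <- tibble::tibble(pn_id = colnames(table$counts),
                           side = table$pn_side,
                           total_synapses = as.numeric(totals))
  if (!is.null(path_lengths)) {
    per_pn$density_per_um <- unname(per_pn$total_synapses /
                                      path_lengths[per_pn$pn_id])
  }
  mean_l <- mean(per_pn$total_synapses[per_pn$side == "L"])
  mean_r <- mean(per_pn$total_synapses[per_pn$side == "R"])
  list(per_pn = per_pn,
       right_vs_left_pct = 100 * (mean_r / mean_l - 1))
}

#' Cross-PN correlations of normalized connection weights
#'
#' For every pair of PNs and every antenna, the Pearson correlation of the
#' antenna-normalized contributions across that antenna's ORNs, with
#' permutation p-values. Shared per-side wiring noise makes same-side PN
#' pairs correlated while opposite-side pairs are not; the same-side family
#' is Holm-corrected.
#'
#' @param table A [connectivity_table()].
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return Tibble: `pn_a`, `pn_b`, `antenna`, `same_side`, `n_orns`, `r`,
#'   `p`, `p_adj` (Holm within the same-side family; opposite-side p's are
#'   reported unadjusted).
#' @export
cross_pn_weight_correlations <- function(table, n_perm = 10000, seed = 1) {
  contrib <- normalized_contributions(table, "per_antenna")
  pns <- colnames(table$counts)
  pairs <- utils::combn(pns, 2, simplify = FALSE)
  rows <- list()
  k <- 0L
  for (ant in c("L", "R")) {
    orns <- rownames(table$counts)[table$orn_side == ant &
                                     table$orn_bilateral]
    # bilateral ORNs of this antenna innervate every PN
    if (length(orns) < 3) {
      abort(paste0("antenna ", ant, " has fewer than 3 ORNs with complete ",
                   "connectivity"))
    }
    wide <- tidyr::pivot_wider(
      dplyr::filter(contrib, .data$antenna == ant,
                    .data$orn_id %in% orns),
      id_cols = "orn_id", names_from = "pn_id", values_from = "pct"
    )
    for (pr in pairs) {
      x <- wide[[pr[1]]]
      y <- wide[[pr[2]]]
      k <- k + 1L
      if (sd(x) == 0 || sd(y) == 0) {
        rows[[k]] <- tibble::tibble(
          pn_a = pr[1], pn_b = pr[2], antenna = ant,
          same_side = table$pn_side[match(pr[1], pns)] ==
            table$pn_side[match(pr[2], pns)],
          n_orns = length(x), r = NA_real_, p = NA_real_, degenerate = TRUE)
        next
      }
      pt <- permutation_test_correlation(x, y, n_perm = n_perm,
                                         seed = seed + k)
      rows[[k]] <- tibble::tibble(
        pn_a = pr[1], pn_b = pr[2], antenna = ant,
        same_side = table$pn_side[match(pr[1], pns)] ==
          table$pn_side[match(pr[2], pns)],
        n_orns = length(x), r = pt$statistic_observed, p = pt$p_value,
        degenerate = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- out$p
  ss <- which(out$same_side & !out$degenerate)
  out$p_adj[ss] <- holm_correction(out$p[ss])
  dplyr::select(out, -"degenerate")
}

#' Synapse-size summary statistics
#'
#' Per-synapse CVs of T-bar volume and contact area, CVs of per-connection
#' means (which shrink roughly as `1/sqrt(synapses per connection)`), the
#' volume-area correlation, and the correlation of per-connection mean size
#' with synapse count.
#'
#' @param geom A synapse geometry table as produced by
#'   [generate_synapse_sizes()]: columns `connection_id`, `tbar_volume_nm3`,
#'   `contact_area_nm2`.
#' @return One-row tibble of CVs and correlations (with p-values from
#'   [stats::cor.test()]).
#' @export
synapse_size_stats <- function(geom) {
  if (length(unique(geom$connection_id)) < 2) {
    abort("need at least 2 connections")
  }
  cv <- function(x) if (mean(x) == 0) 0 else sd(x) / mean(x)
  per_conn <- dplyr::summarise(
    dplyr::group_by(geom, .data$connection_id),
    n_synapses = dplyr::n(),
    mean_volume = mean(.data$tbar_volume_nm3),
    mean_area = mean(.data$contact_area_nm2),
    .groups = "drop"
  )
  vol_area <- stats::cor.test(geom$tbar_volume_nm3, geom$contact_area_nm2)
  const_n <- sd(per_conn$n_synapses) == 0
  size_count <- if (const_n) NULL else
    stats::cor.test(per_conn$mean_volume, per_conn$n_synapses)
  tibble::tibble(
    cv_volume_synapse = cv(geom$tbar_volume_nm3),
    cv_area_synapse = cv(geom$contact_area_nm2),
    cv_volume_connection = cv(per_conn$mean_volume),
    cv_area_connection = cv(per_conn$mean_area),
    r_volume_area = unname(vol_area$estimate),
    p_volume_area = vol_area$p.value,
    r_size_count = if (const_n) NA_real_ else unname(size_count$estimate),
    p_size_count = if (const_n) NA_real_ else size_count$p.value
  )
}
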