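# Reporting surfaces: iteration-correct aggregation, the national burden
# table (scenario x source x disease decomposition), shares and percentage
# reductions, and population-weighted exposure.

agg_keys <- c("city", "tier", "province", "sex", "age_group",
              "disease", "source", "scenario")

# Long iteration matrix + row metadata for one quantity.
iteration_matrix <- function(result, quantity = c("attributable", "reduction"),
                             metric = c("dalys", "economic_loss")) {
  quantity <- match.arg(quantity)
  metric <- match.arg(metric)
  st <- result$strata
  G <- nrow(st)
  if (quantity == "attributable") {
    arr <- result$dalys
    meta <- expand.grid(g = seq_len(G), disease = result$diseases,
                        source = result$sources,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta$scenario <- result$scenario_names[[1]]
  } else {
    arr <- result$rdalys
    meta <- expand.grid(g = seq_len(G), disease = result$diseases,
                        scenario = result$control_names,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta$source <- NA_character_
  }
  V <- matrix(arr, nrow = nrow(meta))
  if (metric == "economic_loss")
    V <- V * st$gdp_per_capita[meta$g]
  meta$city <- st$city_id[meta$g]
  meta$province <- st$province_id[meta$g]
  meta$tier <- st$tier[meta$g]
  meta$age_group <- st$age_group[meta$g]
  meta$sex <- st$sex[meta$g]
  list(values = V, meta = meta)
}

scale_factor <- function(scale = c("raw", "thousand", "billion")) {
  switch(match.arg(scale), raw = 1, thousand = 1e3, billion = 1e9)
}

#' Aggregate Monte Carlo burden results
#'
#' Sums cells within groups per iteration, then summarizes each group's
#' iteration vector (mean, 2.5th and 97.5th percentiles). Percentiles are
#' therefore percentiles of group sums, never sums of percentiles, and the
#' grand total is invariant under any partition.
#'
#' @param result an `no2_mc` from [run_two_stage()].
#' @param by grouping keys, a subset of city, tier, province, sex,
#'   age_group, disease, source, scenario. Empty gives the national total.
#' @param metric `dalys` or `economic_loss`.
#' @param quantity `attributable` (baseline scenario, by source) or
#'   `reduction` (control scenarios).
#' @param scale divide results by 1 (`raw`), 1e3 (`thousand`) or 1e9
#'   (`billion`).
#' @return Data frame with one row per group: grouping columns plus `mean`,
#'   `p2.5`, `p97.5`.
#' @export
aggregate_burden <- function(result, by = character(),
                             metric = c("dalys", "economic_loss"),
                             quantity = c("attributable", "reduction"),
                             scale = c("raw", "thousand", "billion")) {
  bad <- setdiff(by, agg_keys)
  if (length(bad))
    stop_query("unknown grouping key(s): %s; available: %s",
               paste(bad, collapse = ", "), paste(agg_keys, collapse = ", "))
  im <- iteration_matrix(result, quantity, metric)
  sf <- scale_factor(scale)
  if (length(by) == 0) {
    vec <- colSums(im$values) / sf
    s <- summarize_draws(vec)
    return(data.frame(mean = s[["mean"]], p2.5 = s[["p2.5"]],
                      p97.5 = s[["p97.5"]]))
  }
  grp <- interaction(im$meta[by], drop = TRUE, lex.order = TRUE, sep = "\r")
  sums <- rowsum(im$values, grp, reorder = TRUE) / sf
  labels <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  out <- stats::setNames(as.data.frame(labels, stringsAsFactors = FALSE), by)
  out$mean <- rowMeans(sums)
  qs <- t(apply(sums, 1, ui_quantiles))
  out$p2.5 <- qs[, 1]
  out$p97.5 <- qs[, 2]
  rownames(out) <- NULL
  out
}

#' National burden table
#'
#' The headline reporting surface: for the baseline scenario, attributable
#' DALYs and economic losses by source x disease with `total` margin rows
#' and columns; for each control scenario, reductions by disease with a
#' `total` column. All margins are summed per iteration before
#' summarization. No rounding is applied here; see
#' [format_burden_table()] for the presentation conventions.
#'
#' @param x an `no2_mc` result, or a data frame of mean cell values with
#'   columns `scenario`, `source` (NA for control scenarios), `disease`,
#'   `dalys`, `el` — margins are then computed by summation and interval
#'   columns left NA.
#' @param dalys_scale,el_scale unit scaling, see [aggregate_burden()];
#'   defaults report DALYs in thousands and losses in billions.
#' @param ... unused.
#' @return Data frame of class `no2_burden_table` with columns `scenario`,
#'   `source`, `disease`, `dalys`, `dalys_p2.5`, `dalys_p97.5`, `el`,
#'   `el_p2.5`, `el_p97.5`.
#' @export
burden_table <- function(x, ...) UseMethod("burden_table")

bt_units <- function(dalys_scale, el_scale) {
  c(dalys = paste0("DALYs (", dalys_scale, ")"),
    el = paste0("economic losses (", el_scale, " CNY)"))
}

#' @rdname burden_table
#' @export
burden_table.no2_mc <- function(x, dalys_scale = "thousand",
                                el_scale = "billion", ...) {
  cells <- NULL
  add_rows <- function(quantity, by, fixed) {
    d <- aggregate_burden(x, by = by, metric = "dalys", quantity = quantity,
                          scale = dalys_scale)
    e <- aggregate_burden(x, by = by, metric = "economic_loss",
                          quantity = quantity, scale = el_scale)
    row <- cbind(fixed[rep(1, nrow(d)), , drop = FALSE],
                 d[setdiff(names(d), c("mean", "p2.5", "p97.5"))])
    row <- row[!duplicated(names(row))]
    data.frame(row,
               dalys = d$mean, dalys_p2.5 = d$p2.5, dalys_p97.5 = d$p97.5,
               el = e$mean, el_p2.5 = e$p2.5, el_p97.5 = e$p97.5,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  s0 <- x$scenario_names[[1]]
  blank <- function(...) data.frame(..., stringsAsFactors = FALSE)
  cells <- rbind(
    add_rows("attributable", c("source", "disease"),
             blank(scenario = s0)),
    add_rows("attributable", "source",
             blank(scenario = s0, disease = "total")),
    add_rows("attributable", "disease",
             blank(scenario = s0, source = "total")),
    add_rows("attributable", character(),
             blank(scenario = s0, source = "total", disease = "total")),
    add_rows("reduction", c("scenario", "disease"),
             blank(source = NA_character_)),
    add_rows("reduction", "scenario",
             blank(source = NA_character_, disease = "total")))
  cells <- cells[c("scenario", "source", "disease", "dalys", "dalys_p2.5",
                   "dalys_p97.5", "el", "el_p2.5", "el_p97.5")]
  structure(cells, class = c("no2_burden_table", "data.frame"),
            units = bt_units(dalys_scale, el_scale))
}

#' @rdname burden_table
#' @export
burden_table.data.frame <- function(x, dalys_scale = "thousand",
                                    el_scale = "billion", ...) {
  need <- c("scenario", "source", "disease", "dalys", "el")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_input("cell table is missing columns: %s", paste(miss, collapse = ", "))
  cells <- x[!(x$disease %in% "total") &
               !(x$source %in% "total"), need, drop = FALSE]
  margin <- function(df, by, fixed) {
    agg <- stats::aggregate(df[c("dalys", "el")], df[, by, drop = FALSE], sum)
    cbind(fixed[rep(1, nrow(agg)), , drop = FALSE], agg)[
      , c("scenario", "source", "disease", "dalys", "el")]
  }
  s0 <- cells[!is.na(cells$source), , drop = FALSE]
  ctrl <- cells[is.na(cells$source), , drop = FALSE]
  out <- cells
  if (nrow(s0)) {
    out <- rbind(out,
      margin(s0, c("scenario", "source"),
             data.frame(disease = "total", stringsAsFactors = FALSE)),
      margin(s0, c("scenario", "disease"),
             data.frame(source = "total", stringsAsFactors = FALSE)),
      margin(s0, "scenario",
             data.frame(source = "total", disease = "total",
                        stringsAsFactors = FALSE)))
  }
  if (nrow(ctrl)) {
    out <- rbind(out,
      margin(ctrl, c("scenario"),
             data.frame(source = NA_character_, disease = "total",
                        stringsAsFactors = FALSE)))
  }
  out$dalys_p2.5 <- out$dalys_p97.5 <- out$el_p2.5 <- out$el_p97.5 <- NA_real_
  out <- out[c("scenario", "source", "disease", "dalys", "dalys_p2.5",
               "dalys_p97.5", "el", "el_p2.5", "el_p97.5")]
  rownames(out) <- NULL
  structure(out, class = c("no2_burden_table", "data.frame"),
            units = bt_units(dalys_scale, el_scale))
}

bt_cell <- function(bt, scenario, source, disease, col) {
  hit <- bt$scenario == scenario &
    (if (is.na(source)) is.na(bt$source) else !is.na(bt$source) &
       bt$source == source) &
    bt$disease == disease
  v <- bt[[col]][hit]
  if (length(v) != 1) NA_real_ else v
}

#' Percentage reduction of a control scenario
#'
#' `floor(reduction / baseline * 100)`: whole-percent reductions are
#' reported conservatively (floored). A zero baseline gives NA rather than
#' a division error.
#'
#' @param reduction avoided burden in a control scenario.
#' @param baseline total baseline burden (same units).
#' @return Whole percent (floored), or NA if `baseline` is 0.
#' @export
reduction_percent <- function(reduction, baseline) {
  ifelse(baseline == 0, NA_real_, floor(reduction / baseline * 100))
}

#' Shares and scenario reductions from a burden table
#'
#' Disease and source shares of the baseline burden (percent of total
#' DALYs, rounded to whole percent with round-half-even) and the percentage
#' reduction of each control scenario relative to the baseline (floored
#' whole percent), for both DALYs and economic losses. Computed from mean
#' estimates. Zero totals yield NA shares with an `undefined_share`
#' attribute rather than an error.
#'
#' @param bt an `no2_burden_table`.
#' @return List with `disease_share_pct`, `source_share_pct`,
#'   `reduction_pct_dalys`, `reduction_pct_el` (named vectors).
#' @export
shares_and_reductions <- function(bt) {
  if (!inherits(bt, "no2_burden_table"))
    stop_input("bt must be a burden table, see burden_table()")
  s0 <- setdiff(unique(bt$scenario[!is.na(bt$source)]), character(0))[1]
  grand_d <- bt_cell(bt, s0, "total", "total", "dalys")
  grand_e <- bt_cell(bt, s0, "total", "total", "el")
  diseases <- unique(bt$disease[bt$scenario == s0 & bt$disease != "total"])
  sources <- unique(bt$source[bt$scenario == s0 & !is.na(bt$source) &
                                bt$source != "total"])
  share <- function(x, tot) if (is.na(tot) || tot == 0) NA_real_
           else round(x / tot * 100)
  disease_share <- vapply(diseases, function(d)
    share(bt_cell(bt, s0, "total", d, "dalys"), grand_d), 0)
  source_share <- vapply(sources, function(s)
    share(bt_cell(bt, s0, s, "total", "dalys"), grand_d), 0)
  ctrl <- setdiff(unique(bt$scenario), s0)
  red_d <- vapply(ctrl, function(sc)
    reduction_percent(bt_cell(bt, sc, NA, "total", "dalys"), grand_d), 0)
  red_e <- vapply(ctrl, function(sc)
    reduction_percent(bt_cell(bt, sc, NA, "total", "el"), grand_e), 0)
  out <- list(disease_share_pct = disease_share,
              source_share_pct = source_share,
              reduction_pct_dalys = red_d,
              reduction_pct_el = red_e)
  if (anyNA(c(disease_share, source_share, red_d, red_e)))
    attr(out, "undefined_share") <- TRUE
  out
}

fmt_ui <- function(m, lo, hi) {
  f <- function(x) ifelse(is.na(x), "",
                          ifelse(abs(x) < 10, sprintf("%.1f", x),
                                 formatC(round(x), format = "d",
                                         big.mark = ",")))
  ifelse(is.na(lo), f(m), sprintf("%s (%s-%s)", f(m), f(lo), f(hi)))
}

#' Format a burden table for presentation
#'
#' Applies the presentation conventions: values rounded to the table's
#' units (round-half-even; one decimal below 10), uncertainty intervals as
#' "mean (p2.5-p97.5)". Rounding happens only here, never in the
#' underlying estimates.
#'
#' @param bt an `no2_burden_table`.
#' @return Data frame with character columns `dalys` and `economic_losses`.
#' @export
format_burden_table <- function(bt) {
  data.frame(scenario = bt$scenario, source = bt$source,
             disease = bt$disease,
             dalys = fmt_ui(bt$dalys, bt$dalys_p2.5, bt$dalys_p97.5),
             economic_losses = fmt_ui(bt$el, bt$el_p2.5, bt$el_p97.5),
             stringsAsFactors = FALSE)
}

#' Population-weighted NO2 exposure
#'
#' Population-weighted mean of the per-stratum total exposure (sum of the
#' three source means), with an optional 95% population interval: the
#' 2.5th/97.5th percentiles of the individual-level exposure mixture,
#' estimated by drawing `n_per_stratum` individuals per stratum and taking
#' population-weighted quantiles. The interval describes spread across
#' individuals, not sampling uncertainty of the mean.
#'
#' @param exposure exposure table (stratum key + source + mean + sd).
#' @param populations data frame with the stratum key and a `population`
#'   column (the baseline table works; duplicates across diseases are
#'   dropped).
#' @param interval compute the population interval (uses the current RNG).
#' @param n_per_stratum draws per stratum for the interval.
#' @return List with `mean` and, if requested, `p2.5`, `p97.5` (ug/m3).
#' @export
population_weighted_exposure <- function(exposure, populations,
                                         interval = TRUE,
                                         n_per_stratum = 200L) {
  key <- c("city_id", "age_group", "sex")
  pop <- populations[!duplicated(populations[key]), c(key, "population")]
  if (any(pop$population < 0)) stop_input("populations must be non-negative")
  if (sum(pop$population) == 0)
    stop_input("all populations are zero; the weighted exposure is undefined")
  sk <- do.call(paste, pop[key])
  tot <- rowsum(exposure$mean, do.call(paste, exposure[key]))
  m_tot <- tot[match(sk, rownames(tot)), 1]
  if (anyNA(m_tot)) stop_input("exposure table is missing strata present in the population table")
  w <- pop$population / sum(pop$population)
  out <- list(mean = sum(w * m_tot))
  if (interval) {
    ex_sk <- do.call(paste, exposure[key])
    idx_by_stratum <- split(seq_along(ex_sk), ex_sk)
    draws <- lapply(seq_along(sk), function(i) {
      rows <- exposure[idx_by_stratum[[sk[i]]], ]
      s <- sample_individuals(rows, n_per_stratum)
      s$total
    })
    v <- unlist(draws)
    vw <- rep(w / n_per_stratum, each = n_per_stratum)
    ord <- order(v)
    v <- v[ord]; vw <- vw[ord]
    cw <- cumsum(vw) - vw / 2
    out$p2.5 <- stats::approx(cw, v, xout = 0.025, rule = 2)$y
    out$p97.5 <- stats::approx(cw, v, xout = 0.975, rule = 2)$y
  }
  out
}
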