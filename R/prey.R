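#' Mean individuals captured per grid, by vegetation and season-year
#'
#' Summarizes trapping records to the quantity that is quartile-ranked:
#' total individuals divided by the number of grids of that vegetation
#' class, for each (vegetation, season, year).
#'
#' @param records trapping records as returned by [simulate_trapping()]
#'   (columns `grid_id`, `vegetation`, `year`, `session`, `count`).
#' @param session_to_season named map from session label to season label.
#'   The default follows the trapping calendar: the early (May--June)
#'   session indexes summer and the late (August--September) session winter.
#' @return data.frame with `vegetation`, `season`, `year`, `season_year`,
#'   `value` (mean individuals per grid); empty input gives an empty summary.
#' @export
summarize_captures <- function(records,
                               session_to_season = c(early = "summer",
                                                     late = "winter")) {
  if (nrow(records) == 0) {
    return(data.frame(vegetation = character(), season = character(),
                      year = integer(), season_year = character(),
                      value = numeric()))
  }
  if (any(!records$session %in% names(session_to_season))) {
    stop("record has a session label missing from `session_to_season`")
  }
  season <- unname(session_to_season[records$session])
  key <- interaction(records$vegetation, season, records$year, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(records)), key), function(i) {
    data.frame(vegetation = records$vegetation[i[1]],
               season = season[i[1]],
               year = records$year[i[1]],
               value = sum(records$count[i]) / length(unique(records$grid_id[i])))
  }))
  agg$season_year <- season_year_label(agg$season, agg$year)
  rownames(agg) <- NULL
  agg[order(agg$vegetation, agg$year, agg$season),
      c("vegetation", "season", "year", "season_year", "value")]
}

#' Standardize leporid sighting counts by vegetation availability
#'
#' The per-class index is '# of sightings' / '% available': raw counts in a
#' vegetation class divided by the percentage (0--100 scale) of that class
#' available within the 400 m detection strip. A class that is unavailable
#' and unseen gets NA; a sighting in an unavailable class is a data
#' inconsistency.
#'
#' @param counts_by_vegetation named counts of sightings per class.
#' @param availability_percent_by_vegetation named percentages (0--100).
#' @return named numeric index per vegetation class.
#' @export
standardize_leporids <- function(counts_by_vegetation,
                                 availability_percent_by_vegetation) {
  counts <- counts_by_vegetation
  avail <- availability_percent_by_vegetation
  classes <- union(names(counts), names(avail))
  counts <- counts[classes]; counts[is.na(counts)] <- 0
  avail <- avail[classes]; avail[is.na(avail)] <- 0
  names(counts) <- names(avail) <- classes
  bad <- counts > 0 & avail <= 0
  if (any(bad)) {
    stop("data-consistency error: sightings in unavailable vegetation: ",
         paste(classes[bad], collapse = ", "))
  }
  idx <- ifelse(avail > 0, counts / avail, NA_real_)
  names(idx) <- classes
  idx
}

#' Per-season-year leporid indices from sighting records
#'
#' Applies the '# sightings'/'% available' standardization per transect and
#' averages the per-transect indices across the transects on which a class
#' is available, giving one index per (vegetation, season, year).
#'
#' @param sightings data.frame from [simulate_spotlight()] (`transect_id`,
#'   `year`, `season`, `vegetation`).
#' @param transects availability table (`transect_id`, `vegetation`,
#'   `availability` as a proportion in [0,1]).
#' @return data.frame with `vegetation`, `season`, `year`, `season_year`,
#'   `value`.
#' @export
summarize_sightings <- function(sightings, transects) {
  transects$vegetation <- normalize_class(transects$vegetation)
  surveys <- unique(sightings[, c("season", "year")])
  if (nrow(surveys) == 0) {
    return(data.frame(vegetation = character(), season = character(),
                      year = integer(), season_year = character(),
                      value = numeric()))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(surveys)), function(i) {
    sub <- sightings[sightings$season == surveys$season[i] &
                       sightings$year == surveys$year[i], ]
    per_tr <- lapply(split(transects, transects$transect_id), function(tr) {
      cnt <- table(factor(sub$vegetation[sub$transect_id == tr$transect_id[1]],
                          levels = tr$vegetation))
      avail <- tr$availability * 100
      names(avail) <- tr$vegetation
      standardize_leporids(stats::setNames(as.numeric(cnt), tr$vegetation),
                           avail)
    })
    classes <- unique(transects$vegetation)
    vals <- vapply(classes, function(v) {
      x <- vapply(per_tr, function(p) if (v %in% names(p)) p[[v]] else NA_real_,
                  0)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, 0)
    data.frame(vegetation = classes, season = surveys$season[i],
               year = surveys$year[i],
               season_year = season_year_label(surveys$season[i],
                                               surveys$year[i]),
               value = unname(vals))
  }))
  rownames(out) <- NULL
  out
}

#' Quartile abundance ranks (low / medium / high / very high)
#'
#' Values are ranked 1--4 against the quartiles of the pooled set of all
#' summary values for the taxon across the study period: rank 1 (low) for
#' values at or below the 1st quartile, 2 for (Q1, Q2], 3 for (Q2, Q3] and
#' 4 (very high) above Q3. Quartiles use linear interpolation on the sorted
#' pooled values (quantile type 7).
#'
#' @param values numeric vector of summary values (per vegetation x
#'   season-year); NA values receive NA ranks.
#' @param pool optional larger vector to compute the quartiles from (e.g.
#'   the pooled study-period values when ranking one season at a time);
#'   default `values` itself.
#' @return integer vector of ranks in \{1, 2, 3, 4, NA\} with attribute
#'   `thresholds` = c(q1, q2, q3).
#' @export
quartile_rank <- function(values, pool = values) {
  pool <- pool[is.finite(pool)]
  if (!length(pool)) stop("no finite values to rank against")
  q <- quantile(pool, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  rank <- ifelse(is.na(values), NA_integer_,
                 ifelse(values <= q[1], 1L,
                        ifelse(values <= q[2], 2L,
                               ifelse(values <= q[3], 3L, 4L))))
  structure(as.integer(rank), thresholds = q)
}

RANK_LABELS <- c("Low", "Medium", "High", "Very High")

#' Abundance ranking table for one taxon
#'
#' Pools the summary values across all season-years (the study period),
#' computes the quartile thresholds once, and ranks every
#' (vegetation, season_year) cell — the layout mirrors a
#' taxon x vegetation x season-year ranking table.
#'
#' @param summary data.frame from [summarize_captures()] or
#'   [summarize_sightings()].
#' @param taxon "small_mammal" or "leporid".
#' @param pooled pool quartiles across all season-years (default TRUE, the
#'   study-period reading); FALSE computes quartiles within each season.
#' @return an `abundance_ranking`: list with `taxon`, `table` (summary plus
#'   `rank` and `label` columns) and `thresholds`.
#' @export
rank_abundance <- function(summary, taxon = c("small_mammal", "leporid"),
                           pooled = TRUE) {
  taxon <- match.arg(taxon)
  if (pooled) {
    r <- quartile_rank(summary$value)
    thresholds <- attr(r, "thresholds")
  } else {
    r <- rep(NA_integer_, nrow(summary))
    thresholds <- list()
    for (s in unique(summary$season)) {
      i <- summary$season == s
      ri <- quartile_rank(summary$value[i])
      r[i] <- ri
      thresholds[[s]] <- attr(ri, "thresholds")
    }
  }
  tab <- summary
  tab$rank <- as.integer(r)
  tab$label <- RANK_LABELS[tab$rank]
  structure(list(taxon = taxon, table = tab, thresholds = thresholds),
            class = "abundance_ranking")
}

#' Reclassify a vegetation raster to abundance ranks
#'
#' Each cell takes the rank of its vegetation class; classes without a rank
#' become NA (as do nodata cells).
#'
#' @param vegetation categorical `grid_raster`.
#' @param ranking named vector: vegetation class -> rank, or an
#'   `abundance_ranking` plus `season_year` to select the column.
#' @param season_year season-year label when `ranking` is an
#'   `abundance_ranking`.
#' @return continuous `grid_raster` of ranks.
#' @export
reclassify_vegetation <- function(vegetation, ranking, season_year = NULL) {
  if (inherits(ranking, "abundance_ranking")) {
    if (is.null(season_year)) stop("season_year required with a ranking object")
    tab <- ranking$table[ranking$table$season_year == season_year, ]
    ranking <- stats::setNames(tab$rank, tab$vegetation)
  }
  names(ranking) <- normalize_class(names(ranking))
  lut <- rep(NA_real_, length(vegetation$levels))
  hit <- match(names(ranking), vegetation$levels)
  lut[hit[!is.na(hit)]] <- as.numeric(ranking[!is.na(hit)])
  raster_apply(vegetation, function(v) {
    out <- matrix(NA_real_, nrow(v), ncol(v))
    ok <- !is.na(v)
    out[ok] <- lut[v[ok]]
    out
  })
}

#' Combine small-mammal and leporid rank rasters into one prey layer
#'
#' Weighted mean of the two rank rasters (default weights 2/3 small mammal,
#' 1/3 leporid, reflecting their contribution to the focal predator's diet).
#' Where exactly one taxon is ranked, that rank is used alone (weight
#' renormalized to 1) so the larger NA footprint of the leporid layer does
#' not erase small-mammal information; `strict = TRUE` propagates NA
#' instead. Both NA stays NA.
#'
#' @param sm_rank,lep_rank aligned rank `grid_raster`s.
#' @param weights length-2 numeric summing to 1 (small mammal, leporid).
#' @param strict propagate NA when either input is NA.
#' @return a `prey_raster`: `grid_raster` with attributes `weights`.
#' @export
combine_prey <- function(sm_rank, lep_rank, weights = c(2 / 3, 1 / 3),
                         strict = FALSE) {
  if (!rasters_aligned(sm_rank, lep_rank)) {
    stop("alignment error: prey rank rasters are on different grids")
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  a <- sm_rank$values; b <- lep_rank$values
  out <- weights[1] * a + weights[2] * b
  if (!strict) {
    only_a <- !is.na(a) & is.na(b)
    only_b <- is.na(a) & !is.na(b)
    out[only_a] <- a[only_a]
    out[only_b] <- b[only_b]
  }
  r <- grid_raster(out, sm_rank$cell_size, sm_rank$origin)
  attr(r, "weights") <- weights
  r
}
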