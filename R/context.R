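#' Euphotic-zone depth from Kd490
#'
#' Depth of the 1% light level estimated from the diffuse attenuation
#' coefficient for downward irradiance at 490 nm: `Zeu = 4.6 / Kd490`
#' (meters; Kd490 in 1/m). Nonpositive or missing Kd490 leaves the field
#' empty.
#'
#' @param kd490 numeric vector, 1/m
#' @return numeric vector of depths in meters (NA where undefined)
#' @export
euphotic_depth <- function(kd490) {
  out <- rep(NA_real_, length(kd490))
  ok <- !is.na(kd490) & kd490 > 0
  out[ok] <- 4.6 / kd490[ok]
  out
}

#' Read province polygons from GeoJSON
#'
#' Supports FeatureCollections of Polygon/MultiPolygon features with a
#' province code in `properties` (first property used, or `code`). Only
#' outer rings are used; antimeridian-crossing polygons must be pre-split.
#'
#' @param path GeoJSON file
#' @return named list of polygons, each a matrix with columns lon, lat
#' @export
read_provinces <- function(path) {
  g <- jsonlite::read_json(path)
  out <- list()
  for (f in g$features) {
    props <- f$properties
    code <- if (!is.null(props$code)) props$code else props[[1L]]
    rings <- if (f$geometry$type == "Polygon") list(f$geometry$coordinates)
             else if (f$geometry$type == "MultiPolygon") f$geometry$coordinates
             else stop("unsupported geometry type: ", f$geometry$type)
    for (ring in rings) {
      outer <- ring[[1L]]
      m <- do.call(rbind, lapply(outer, function(p)
        c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))))
      colnames(m) <- c("lon", "lat")
      nm <- as.character(code)
      while (nm %in% names(out)) nm <- paste0(nm, "_")
      out[[nm]] <- m
    }
  }
  out
}

# even-odd ray casting; boundary handling is approximate (a point exactly
# on an edge counts for the first-listed containing province)
point_in_polygon <- function(lon, lat, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    if ((yi > lat) != (yj > lat)) {
      xint <- (xj - xi) * (lat - yi) / (yj - yi) + xi
      if (lon < xint) inside <- !inside
      else if (lon == xint) return(TRUE)  # on a boundary edge
    }
    j <- i
  }
  inside
}

#' Assign samples to provinces by point-in-polygon
#'
#' Even-odd ray-casting containment against user-supplied province
#' polygons (e.g. Longhurst biogeochemical provinces). Points contained in
#' no polygon are `NA`; points on a shared boundary resolve to the
#' first-listed containing province.
#'
#' @param lat,lon numeric vectors of sample coordinates; lon in [-180, 180]
#' @param provinces named polygon list from [read_provinces()]
#' @return character vector of province codes (NA when unassigned)
#' @export
assign_longhurst <- function(lat, lon, provinces) {
  stopifnot(length(lat) == length(lon))
  for (p in provinces) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 4L)
      stop("malformed polygon: need a closed ring of >= 4 lon/lat points")
  }
  vapply(seq_along(lat), function(i) {
    for (nm in names(provinces)) {
      if (point_in_polygon(lon[i], lat[i], provinces[[nm]])) return(nm)
    }
    NA_character_
  }, character(1))
}

#' Meteorological season of a sample
#'
#' DJF/MAM/JJA/SON seasons, flipped for the southern hemisphere
#' (`lat < 0`), so a July sample is Summer at 40N and Winter at 40S.
#'
#' @param datetime Date, POSIXt, or string parseable by [as.Date()]
#' @param lat decimal latitude
#' @return character: Winter, Spring, Summer or Autumn
#' @export
season_of <- function(datetime, lat) {
  mo <- as.integer(format(as.Date(datetime), "%m"))
  north <- c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer",
             "Summer", "Summer", "Autumn", "Autumn", "Autumn", "Winter")
  flip <- c(Winter = "Summer", Spring = "Autumn", Summer = "Winter",
            Autumn = "Spring")
  s <- north[mo]
  ifelse(lat < 0, unname(flip[s]), s)
}

#' Read a sample metadata table
#'
#' TSV with at least sample_id, lat, lon, depth; optional Date, Kd490 and
#' the environmental covariate columns (Temperature, Salinity, Oxygen,
#' NO2, NO3, NH3, PO4, Silicate, DOC, TOC, PAR, Chlorophyll). Derives
#' `zeu` from Kd490 where present.
#'
#' @param path metadata TSV
#' @return `data.table`
#' @export
read_metadata <- function(path) {
  m <- data.table::fread(path, sep = "\t")
  stopifnot(all(c("sample_id", "lat", "lon", "depth") %in% names(m)))
  if ("Kd490" %in% names(m)) m[, zeu := euphotic_depth(Kd490)]
  m
}

#' Per-sample and stratum-mean group relative abundances
#'
#' Sums corrected abundances by group within each sample, normalizes to
#' per-sample fractions (which sum to 1 over groups), and reports the
#' unweighted mean fraction across the selected samples. The `five_major`
#' grouping collapses the eco groups into archaea, bacteria (minus
#' cyanobacteria), cyanobacteria, chloroplast 16S and eukaryotic 18S.
#'
#' @param table a `corrected_asv_table`
#' @param taxonomy output of [classify_table()] (needs asv_id and
#'   `Eco_relevant_plank_groups`)
#' @param grouping `"eco_groups"` or `"five_major"`
#' @param samples optional character vector selecting a stratum (default
#'   all samples in the table)
#' @return list with `per_sample` (long `data.table`: sample_id, group,
#'   fraction) and `mean` (group -> mean fraction)
#' @export
group_relative_abundance <- function(table, taxonomy,
                                     grouping = c("eco_groups", "five_major"),
                                     samples = NULL) {
  grouping <- match.arg(grouping)
  if (is.null(samples)) samples <- rownames(table$counts)
  samples <- intersect(samples, rownames(table$counts))
  if (length(samples) == 0L)
    stop("empty stratum: no samples selected")
  grp <- setNames(taxonomy$Eco_relevant_plank_groups, taxonomy$asv_id)
  if (grouping == "five_major") {
    five <- function(g, pool) {
      if (g == "Archaea") "Archaea"
      else if (g == "Cyanobacteria") "Cyanobacteria"
      else if (g == "Chloroplast 16S") "Chloroplast 16S"
      else if (pool == "SSU18S") "Eukaryote 18S"
      else "Bacteria"
    }
    grp <- setNames(
      vapply(taxonomy$asv_id, function(a)
        five(grp[[a]], table$pool[[a]]), character(1)),
      taxonomy$asv_id)
  }
  asvs <- colnames(table$counts)
  miss <- setdiff(asvs, names(grp))
  if (length(miss)) stop("ASVs without a group: ", length(miss))
  lev <- sort(unique(unname(grp[asvs])))
  per <- data.table::rbindlist(lapply(samples, function(sid) {
    v <- table$counts[sid, , drop = TRUE]
    tot <- sum(v)
    agg <- tapply(v, factor(grp[asvs], levels = lev), sum)
    agg[is.na(agg)] <- 0
    data.table::data.table(sample_id = sid, group = lev,
                           fraction = if (tot > 0) as.numeric(agg) / tot
                                      else NA_real_)
  }))
  mean_frac <- per[, .(mean_fraction = mean(fraction)), by = group]
  list(per_sample = per, mean = setNames(mean_frac$mean_fraction,
                                         mean_frac$group))
}
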