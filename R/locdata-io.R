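#' Read a localisation table from its CSV dialect
#'
#' The on-disk dialect is a comma-separated UTF-8 file with "." as decimal
#' separator, optional leading metadata comment lines `# key=value`, and the
#' header `id,channel,frame,x_nm,y_nm,z_nm,photons,bg,sigma_xy_nm,
#' sigma_z_nm[,cluster_id]`. Unknown extra columns are preserved as opaque
#' character columns. All coordinates are in nanometres and are not
#' converted. Ids are assigned densely in file order.
#'
#' @param path path to a CSV file in the dialect above
#' @param meta_override optional named list merged over the file's metadata
#' @return a [LocalizationTable-class]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' tb <- localizationTable(data.frame(
#'   channel = c("bassoon", "Homer1"), frame = 0L,
#'   x_nm = c(0, 120), y_nm = 0, z_nm = 0, photons = 1000, bg = 5,
#'   sigma_xy_nm = 10, sigma_z_nm = 25))
#' writeLocalizations(tb, f)
#' nLocs(readLocalizations(f))
#' @export
readLocalizations <- function(path, meta_override = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ml in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      meta[[key]] <- if (key == "channels") strsplit(val, ",")[[1]]
                     else if (key == "source") val
                     else suppressWarnings(as.numeric(val))
    }
  }
  body <- lines[!is_meta]
  if (length(body) == 0L) stop("file has no header row: ", path)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  mandatory <- setdiff(.LOC_COLS, "id")
  miss <- setdiff(c("id", mandatory), header)
  if (length(miss))
    stop("missing mandatory column '", miss[1], "' in ", path)
  nrec <- length(body) - 1L
  if (nrec == 0L) {
    d <- as.data.frame(setNames(rep(list(character(0)), length(header)), header))
  } else {
    d <- utils::read.csv(text = paste(body, collapse = "\n"),
                         colClasses = "character", check.names = FALSE)
  }
  num_cols <- intersect(c(.LOC_NM_COLS, "frame", "cluster_id"), header)
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !(d[[col]] %in% c("NA", "")))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ", bad[1],
           " of ", path)
    if (col %in% c("x_nm", "y_nm", "z_nm") && anyNA(v))
      stop("non-numeric value in column '", col, "' at data row ",
           which(is.na(v))[1], " of ", path)
    d[[col]] <- if (col %in% c("frame", "cluster_id")) as.integer(v) else v
  }
  d$id <- NULL
  for (key in names(meta_override)) meta[[key]] <- meta_override[[key]]
  localizationTable(d, meta)
}

#' Write a localisation table in the canonical CSV dialect
#'
#' Canonical form: metadata comment lines (`pixel_size_nm`,
#' `axial_range_nm`, `channels`, `source`, in that order), the fixed-order
#' header, nm and photon fields with 6 decimal places, `\n` newlines. The
#' `cluster_id` column is written only when cluster assignment is set.
#' Reading a canonical file and writing it again reproduces it byte for
#' byte.
#'
#' @param table a [LocalizationTable-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeLocalizations <- function(table, path) {
  stopifnot(is(table, "LocalizationTable"))
  validObject(table)
  d <- table@data
  meta <- table@meta
  hdr <- c(
    sprintf("# pixel_size_nm=%g", meta$pixel_size_nm),
    sprintf("# axial_range_nm=%g", meta$axial_range_nm),
    sprintf("# channels=%s", paste(meta$channels, collapse = ",")),
    sprintf("# source=%s", meta$source))
  cols <- .LOC_COLS
  if (!is.null(d$cluster_id)) cols <- c(cols, "cluster_id")
  extra <- setdiff(names(d), c(cols, "cluster_id"))
  cols <- c(cols, extra)
  fields <- lapply(cols, function(col) {
    v <- d[[col]]
    if (col %in% .LOC_NM_COLS) fmt6(v)
    else if (col %in% c("id", "frame", "cluster_id")) format(as.integer(v),
                                                             trim = TRUE)
    else as.character(v)
  })
  rows <- if (nrow(d)) do.call(paste, c(fields, sep = ",")) else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(cols, collapse = ","), rows), con, sep = "\n")
  invisible(path)
}

#' Subset a localisation table to one channel
#'
#' The subset gets fresh dense ids; the original ids are preserved in an
#' `orig_id` provenance column (original `orig_id` is kept if already
#' present, so provenance always points at the table first read or
#' simulated). Metadata is unchanged.
#'
#' @param table a [LocalizationTable-class]
#' @param channel a channel label present in `meta$channels`
#' @return a [LocalizationTable-class] with the matching records
#' @export
filterByChannel <- function(table, channel) {
  ch <- table@meta$channels
  if (!channel %in% ch)
    stop("unknown channel '", channel, "'; valid channels: ",
         paste(ch, collapse = ", "))
  d <- table@data
  keep <- d$channel == channel
  sub <- d[keep, , drop = FALSE]
  if (is.null(sub$orig_id)) sub$orig_id <- sub$id
  localizationTable(sub, table@meta)
}

#' Write per-cluster morphometry to CSV
#'
#' Columns: `cluster_id,channel,n_locs,cx_nm,cy_nm,cz_nm,hull_volume_nm3,
#' density_per_um3`.
#'
#' @param clusters a [ClusterSet-class] or list of them
#' @param path output path
#' @return invisibly, the path
#' @export
writeClusters <- function(clusters, path) {
  if (is(clusters, "ClusterSet")) clusters <- list(clusters)
  s <- do.call(rbind, lapply(clusters, clusterSummary))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("cluster_id,channel,n_locs,cx_nm,cy_nm,cz_nm,hull_volume_nm3,density_per_um3",
               if (nrow(s)) sprintf("%d,%s,%d,%s,%s,%s,%s,%s",
                 s$cluster_id, s$channel, s$n_locs, fmt6(s$cx_nm),
                 fmt6(s$cy_nm), fmt6(s$cz_nm), fmt6(s$hull_volume_nm3),
                 ifelse(is.na(s$density_per_um3), "NA",
                        fmt6(s$density_per_um3)))),
             con, sep = "\n")
  invisible(path)
}

#' Write distance sets to CSV
#'
#' Columns: `kind,distance_nm,synapse_id` (empty synapse id when a distance
#' is not tied to one synapse).
#'
#' @param dsets a [DistanceSet-class] or list of them
#' @param path output path
#' @return invisibly, the path
#' @export
writeDistances <- function(dsets, path) {
  if (is(dsets, "DistanceSet")) dsets <- list(dsets)
  con <- file(path, open = "wb")
  on.exit(close(con))
  rows <- unlist(lapply(dsets, function(ds) {
    if (!length(ds@distances_nm)) return(character(0))
    sprintf("%s,%s,%s", ds@kind, fmt6(ds@distances_nm),
            ifelse(is.na(ds@synapse_id), "", as.character(ds@synapse_id)))
  }))
  writeLines(c("kind,distance_nm,synapse_id", rows), con, sep = "\n")
  invisible(path)
}

#' Read a pipeline/simulation configuration from YAML
#'
#' @param path path to a YAML file
#' @return named list of configuration sections
#' @export
readConfigYaml <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  yaml::read_yaml(path)
}
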