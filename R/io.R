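#' Read and write layouts, rasters and connectomes
#'
#' Tabular text is the interchange format (one row per neuron / spike /
#' edge, tab-separated, `#`-prefixed header lines carrying metadata); an
#' RDS container with identical content is available via `format`.
#'
#' @param layout,raster,connectome objects to serialize.
#' @param path file path.
#' @param format `"tsv"` (plain text) or `"rds"`.
#' @name ca3net_io
NULL

#' @rdname ca3net_io
#' @export
write_layout <- function(layout, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(invisible(saveRDS(layout, path)))
  geom <- attr(layout, "geometry")
  hdr <- c(
    sprintf("# seed=%d", attr(layout, "seed")),
    vapply(names(geom), function(s)
      sprintf("# extent %s %g %g", s, geom[[s]][["longitudinal"]],
              geom[[s]][["transverse"]]), character(1))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(layout), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ca3net_io
#' @export
read_layout <- function(path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  seed <- as.integer(sub("# seed=", "", hdr[startsWith(hdr, "# seed=")]))
  ext <- hdr[startsWith(hdr, "# extent")]
  geom <- default_geometry()
  for (h in ext) {
    f <- strsplit(h, " +")[[1]]
    geom[[f[3]]] <- c(longitudinal = as.numeric(f[4]),
                      transverse = as.numeric(f[5]))
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(df, geometry = geom, seed = seed,
            class = c("ca3net_layout", "data.frame"))
}

#' @rdname ca3net_io
#' @export
write_raster <- function(raster, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(invisible(saveRDS(raster, path)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# duration=%g", raster$duration),
               sprintf("# population=%s", raster$population),
               sprintf("# n_neurons=%d", length(raster$trains)),
               sprintf("# ids=%s", paste(raster$ids, collapse = ","))),
             con)
  ns <- vapply(raster$trains, length, integer(1))
  if (sum(ns)) {
    df <- data.frame(neuron_id = rep.int(raster$ids, ns),
                     spike_time_ms = unlist(raster$trains,
                                            use.names = FALSE))
    utils::write.table(df, con, sep = "\t", row.names = FALSE,
                       col.names = c("neuron_id", "spike_time_ms"),
                       quote = FALSE)
  } else {
    writeLines("neuron_id\tspike_time_ms", con)
  }
  invisible(path)
}

#' @rdname ca3net_io
#' @export
read_raster <- function(path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("# ", key, "="), "",
                           hdr[startsWith(hdr, paste0("# ", key, "="))])
  duration <- as.numeric(get("duration"))
  population <- get("population")
  ids <- as.integer(strsplit(get("ids"), ",")[[1]])
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  trains <- lapply(ids, function(i)
    df$spike_time_ms[df$neuron_id == i])
  spike_raster(trains, duration, population = population, ids = ids)
}

#' @rdname ca3net_io
#' @export
write_connectome <- function(connectome, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(invisible(saveRDS(connectome, path)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed=%d", connectome$seed),
               sprintf("# mf_dropped=%d", connectome$mf_dropped)), con)
  utils::write.table(connectome$edges, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ca3net_io
#' @export
read_connectome <- function(path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  seed <- as.integer(sub("# seed=", "", hdr[startsWith(hdr, "# seed=")]))
  dropped <- as.integer(sub("# mf_dropped=", "",
                            hdr[startsWith(hdr, "# mf_dropped=")]))
  edges <- utils::read.table(text = lines[!startsWith(lines, "#")],
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  structure(list(edges = edges, mf_dropped = dropped, seed = seed,
                 config = NULL,
                 summary = stats::aggregate(
                   list(n_edges = edges$pre_id),
                   by = list(pathway = edges$pathway), FUN = length)),
            class = "ca3net_connectome")
}
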