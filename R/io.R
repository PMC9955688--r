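#' Serialize an RBN model to JSON
#'
#' The document stores `n_nodes`, 0-based `in_neighbors`, per-node `bias`,
#' per-node `tables` as bitstrings (most significant bit = first listed
#' in-neighbor), and `meta`. Nodes with hashed rules (in-degree beyond the
#' table threshold) store their 64-bit hash seed instead of a bitstring.
#' The round-trip through [read_rbn_model()] is lossless.
#'
#' @param model an `rbn_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rbn_model <- function(model, path) {
  stopifnot(inherits(model, "rbn_model"))
  n <- model$topology$n_nodes
  tables <- lapply(seq_len(n), function(a) {
    if (model$rules$hashed[a]) {
      list(hash_seed_hi = model$rules$seed_hi[a],
           hash_seed_lo = model$rules$seed_lo[a])
    } else {
      paste(model$rules$tables[[a]], collapse = "")
    }
  })
  doc <- list(
    n_nodes = n,
    in_neighbors = lapply(model$topology$in_neighbors, function(v) v - 1L),
    bias = sprintf("%.17g", model$rules$bias),
    tables = tables,
    meta = model$meta
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an RBN model from JSON
#'
#' @param path file written by [write_rbn_model()].
#' @return an `rbn_model`.
#' @export
read_rbn_model <- function(path) {
  doc <- jsonlite::read_json(path)
  n <- doc$n_nodes
  inn <- lapply(doc$in_neighbors, function(v) as.integer(unlist(v)) + 1L)
  if (length(inn) != n) stop("malformed model file", call. = FALSE)
  bias <- as.numeric(unlist(doc$bias))
  tables <- vector("list", n)
  hashed <- logical(n)
  seed_hi <- integer(n); seed_lo <- integer(n)
  for (a in seq_len(n)) {
    tb <- doc$tables[[a]]
    if (is.character(tb)) {
      tables[[a]] <- as.integer(strsplit(tb, "")[[1]])
    } else {
      hashed[a] <- TRUE
      seed_hi[a] <- as.integer(tb$hash_seed_hi)
      seed_lo[a] <- as.integer(tb$hash_seed_lo)
    }
  }
  topology <- new_topology(n, inn)
  rules <- structure(list(bias = bias, tables = tables, hashed = hashed,
                          seed_hi = seed_hi, seed_lo = seed_lo,
                          max_table_k = getOption("rbnhet.max_table_k", 16L)),
                     class = "rbn_rules")
  structure(list(topology = topology, rules = rules,
                 meta = doc$meta),
            class = "rbn_model")
}

#' Write a trajectory as a plain-text 0/1 CSV matrix
#'
#' One row per time step, comma-separated bits, no header.
#'
#' @param traj an `rbn_trajectory` (T x N matrix).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.table(unclass(traj), path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#' @param path file path.
#' @return an `rbn_trajectory` matrix.
#' @export
read_trajectory <- function(path) {
  m <- as.matrix(read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  structure(m, class = c("rbn_trajectory", class(m)))
}

#' Render a trajectory raster image
#'
#' One pixel per node state, time flowing downward from the initial state
#' at the top; expressed (1) states are drawn dark.
#'
#' @param traj an `rbn_trajectory`.
#' @param path optional PNG output path; when `NULL`, draws on the current
#'   graphics device.
#' @param scale integer pixel scale per state cell (PNG output).
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_trajectory <- function(traj, path = NULL, scale = 3) {
  draw <- function() {
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit(graphics::par(op))
    # transpose + reverse rows so time runs top to bottom
    z <- t(unclass(traj))[, rev(seq_len(nrow(traj))), drop = FALSE]
    graphics::image(z, col = c("white", "black"), axes = FALSE,
                    useRaster = TRUE)
  }
  if (is.null(path)) {
    draw()
  } else {
    grDevices::png(path, width = ncol(traj) * scale,
                   height = nrow(traj) * scale)
    on.exit(grDevices::dev.off())
    draw()
  }
  invisible(path)
}

#' Export a curve as CSV with a JSON provenance sidecar
#'
#' The CSV holds columns `x`, `y_mean`, `y_se`, `n_reps`; the sidecar
#' (`<path>.json`) holds the full generating configuration including the
#' master seed, sufficient to re-run any single point exactly.
#'
#' @param curve an `rbn_curve`.
#' @param path CSV output path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, sidecar = TRUE) {
  write.table(as.data.frame(curve), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  if (sidecar) {
    jsonlite::write_json(list(label = attr(curve, "label"),
                              config = attr(curve, "config")),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a curve CSV written by [write_curve()]
#' @param path CSV file path.
#' @return an `rbn_curve` (provenance attributes restored from the sidecar
#'   when present).
#' @export
read_curve <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  label <- NULL; config <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    doc <- jsonlite::read_json(sidecar)
    label <- doc$label; config <- doc$config
  }
  new_curve(df$x, df$y_mean, df$y_se, df$n_reps[1], label, config)
}

#' Plot a set of curves
#'
#' Convenience line plot of one or more `rbn_curve`s (complexity or
#' fragility versus the swept parameter) with +/- 1 SE ribbons when
#' ggplot2 is available.
#'
#' @param curves a single `rbn_curve` or a named list of them.
#' @param xlab,ylab axis labels.
#' @return a ggplot object (if ggplot2 is installed) or `NULL` after
#'   drawing with base graphics.
#' @export
plot_curves <- function(curves, xlab = "K", ylab = "C") {
  if (inherits(curves, "rbn_curve")) curves <- list(curve = curves)
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    data.frame(label = nm, x = cv$x, y = cv$y_mean, se = cv$y_se)
  }))
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = label,
                                     fill = label)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = y - se, ymax = y + se),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::labs(x = xlab, y = ylab, colour = NULL, fill = NULL) +
      ggplot2::theme_minimal()
  } else {
    graphics::matplot(matrix(df$x, ncol = length(curves)),
                      matrix(df$y, ncol = length(curves)),
                      type = "l", lty = 1, xlab = xlab, ylab = ylab)
    graphics::legend("topright", legend = names(curves),
                     col = seq_along(curves), lty = 1, cex = 0.7)
    invisible(NULL)
  }
}

#' Read a flat run configuration (JSON or YAML)
#'
#' Keys mirror the generator and experiment arguments, e.g.
#' `structural.kind`, `structural.mean_k`, `functional.kind`,
#' `functional.mean`, `functional.sd`, `functional.domain`, plus experiment
#' settings (`n_nodes`, `n_steps`, `seed`, ...). YAML files require the
#' yaml package.
#'
#' @param path config file (`.json`, `.yaml`, or `.yml`).
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::yaml.load_file(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Build generator specs from a flat config list
#'
#' @param config list with `structural.kind`, `structural.mean_k`, and
#'   optional `functional.*` keys (either nested lists or flat dotted
#'   names).
#' @return list with elements `structural` ([degree_spec()]) and
#'   `functional` ([bias_spec()]).
#' @export
specs_from_config <- function(config) {
  get_key <- function(cfg, outer, inner, default = NULL) {
    flat <- cfg[[paste(outer, inner, sep = ".")]]
    if (!is.null(flat)) return(flat)
    nested <- cfg[[outer]]
    if (!is.null(nested) && !is.null(nested[[inner]])) return(nested[[inner]])
    default
  }
  structural <- degree_spec(get_key(config, "structural", "kind", "poisson"),
                            get_key(config, "structural", "mean_k", 2))
  functional <- bias_spec(get_key(config, "functional", "kind", "point"),
                          mean = get_key(config, "functional", "mean", 0.5),
                          sd = get_key(config, "functional", "sd", 0),
                          domain = as.numeric(get_key(config, "functional",
                                                      "domain", c(0, 1))))
  list(structural = structural, functional = functional)
}
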