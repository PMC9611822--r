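#' Read / write tab-separated tables with metadata headers
#'
#' The package's on-disk interchange format: a plain TSV with a header row,
#' preceded by optional \code{#key=value} metadata lines. \code{write_table}
#' then \code{read_table} round-trips numeric values to full double
#' precision. A schema (named character vector of column types,
#' \code{"numeric"} or \code{"character"}) can be enforced on read; a
#' missing column raises an error naming it. A header-only file yields an
#' empty record set, not an error.
#'
#' @param path file path.
#' @param schema optional named character vector, e.g.
#'   \code{c(r_nm = "numeric", der = "numeric")}.
#' @param records data.frame to write.
#' @param metadata named list written as \code{#key=value} lines.
#' @return \code{read_table}: a data.frame with attribute \code{"metadata"}
#'   (named character vector). \code{write_table}: \code{path}, invisibly.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- character(0)
  if (length(meta_lines)) {
    kv <- sub("^#\\s*", "", meta_lines)
    has_eq <- grepl("=", kv, fixed = TRUE)
    meta <- stats::setNames(sub("^[^=]*=", "", kv[has_eq]),
                            sub("=.*$", "", kv[has_eq]))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) == 0) stop("no header line in ", path)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(names(schema), names(df))
    if (length(miss))
      stop("missing column '", miss[1], "' in ", path)
    for (cn in names(schema)) {
      if (schema[[cn]] == "numeric") {
        v <- suppressWarnings(as.numeric(df[[cn]]))
        bad <- which(is.na(v) & !is.na(df[[cn]]))
        if (length(bad))
          stop(sprintf("non-numeric value in row %d, column '%s' of %s",
                       bad[1], cn, path))
        df[[cn]] <- v
      } else {
        df[[cn]] <- as.character(df[[cn]])
      }
    }
  }
  attr(df, "metadata") <- meta
  df
}

#' @rdname read_table
#' @export
write_table <- function(records, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("#%s=%s", k, format(metadata[[k]], digits = 17)), con)
  utils::write.table(format(records, digits = 17, trim = TRUE,
                            scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write DER kernel files
#'
#' TSV with columns \code{r_nm}, \code{der} and a \code{#support_max_nm=}
#' metadata line.
#'
#' @param profile a \code{\link{der_profile}}.
#' @param path file path.
#' @return \code{read_kernel}: a \code{\link{der_profile}};
#'   \code{write_kernel}: \code{path}, invisibly.
#' @export
write_kernel <- function(profile, path) {
  stopifnot(inherits(profile, "der_profile"))
  meta <- list(support_max_nm = profile$support_max)
  if (!is.null(profile$edges))
    meta$edges_nm <- paste(format(profile$edges, digits = 17, trim = TRUE),
                           collapse = ",")
  write_table(data.frame(r_nm = profile$radii, der = profile$der), path, meta)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  df <- read_table(path, schema = c(r_nm = "numeric", der = "numeric"))
  meta <- attr(df, "metadata")
  support <- if ("support_max_nm" %in% names(meta))
    as.numeric(meta[["support_max_nm"]]) else max(df$r_nm)
  edges <- if ("edges_nm" %in% names(meta))
    as.numeric(strsplit(meta[["edges_nm"]], ",")[[1]]) else NULL
  der_profile(df$r_nm, df$der, support_max = support, edges = edges)
}

#' Read / write nanoparticle placement files
#'
#' TSV with columns \code{x_um}, \code{y_um}; metadata lines carry the
#' placement mode, seed and geometry.
#'
#' @param placement an \code{\link{np_placement}}.
#' @param path file path.
#' @return \code{read_placement}: an \code{\link{np_placement}};
#'   \code{write_placement}: \code{path}, invisibly.
#' @export
write_placement <- function(placement, path) {
  stopifnot(inherits(placement, "np_placement"))
  g <- placement$geometry
  write_table(data.frame(x_um = placement$positions[, 1],
                         y_um = placement$positions[, 2]),
              path,
              list(mode = placement$mode, seed = placement$seed,
                   ecm_side_um = g$ecm_side,
                   cell_diameter_um = g$cell_diameter,
                   nucleus_diameter_um = g$nucleus_diameter))
}

#' @rdname write_placement
#' @export
read_placement <- function(path) {
  df <- read_table(path, schema = c(x_um = "numeric", y_um = "numeric"))
  meta <- attr(df, "metadata")
  geometry <- cell_geometry(
    ecm_side = as.numeric(meta[["ecm_side_um"]]),
    cell_diameter = as.numeric(meta[["cell_diameter_um"]]),
    nucleus_diameter = as.numeric(meta[["nucleus_diameter_um"]]))
  pos <- cbind(x = df$x_um, y = df$y_um)
  structure(list(positions = pos, mode = meta[["mode"]],
                 seed = as.integer(meta[["seed"]]), geometry = geometry),
            class = "np_placement")
}

#' Read / write particle spectrum files
#'
#' TSV with columns \code{ptype} (photon/electron), \code{energy_MeV},
#' \code{weight}, \code{cos_theta}.
#'
#' @param spectrum an \code{\link{energy_spectrum}}.
#' @param path file path.
#' @return \code{read_spectrum}: an \code{\link{energy_spectrum}};
#'   \code{write_spectrum}: \code{path}, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  write_table(data.frame(ptype = spectrum$particle_type,
                         energy_MeV = spectrum$energy,
                         weight = spectrum$weight,
                         cos_theta = spectrum$cos_theta), path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- read_table(path, schema = c(ptype = "character",
                                    energy_MeV = "numeric",
                                    weight = "numeric",
                                    cos_theta = "numeric"))
  energy_spectrum(df$ptype, df$energy_MeV, df$weight, df$cos_theta)
}

#' Read / write survival curve files
#'
#' TSV with columns \code{dose_Gy}, \code{sf_mean}, \code{sf_sd},
#' \code{n_replicates}.
#'
#' @param curve a \code{\link{survival_curve}}.
#' @param path file path.
#' @return \code{read_curve}: a \code{\link{survival_curve}};
#'   \code{write_curve}: \code{path}, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  nrep <- if ("n_replicates" %in% names(curve)) curve$n_replicates else NA
  sfsd <- if ("sf_sd" %in% names(curve)) curve$sf_sd else NA_real_
  write_table(data.frame(dose_Gy = curve$dose_Gy, sf_mean = curve$sf,
                         sf_sd = sfsd, n_replicates = nrep),
              path, list(source = attr(curve, "source")))
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read_table(path, schema = c(dose_Gy = "numeric", sf_mean = "numeric"))
  meta <- attr(df, "metadata")
  src <- if ("source" %in% names(meta)) meta[["source"]] else "experiment"
  se <- if ("sf_sd" %in% names(df) && "n_replicates" %in% names(df))
    suppressWarnings(as.numeric(df$sf_sd) / sqrt(as.numeric(df$n_replicates)))
  else NULL
  survival_curve(df$dose_Gy, df$sf_mean, sf_se = se, source = src)
}

#' Read clonogenic assay CSV files
#'
#' CSV with header \code{group,dose_Gy,n_seeded,n_colonies,replicate}.
#'
#' @param path file path.
#' @return A \code{\link{clonogenic_records}} data.frame.
#' @export
read_clonogenic <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  clonogenic_records(df)
}

default_config <- function() {
  list(
    geometry = list(ecm_side_um = 17.5, cell_diameter_um = 13.5,
                    nucleus_diameter_um = 8),
    load = list(count = 800, mass_per_cell_pg = NULL, weight_percent = NULL,
                np_diameter_nm = 15, slice_fraction = 1.0),
    placement = list(mode = "cytoplasm"),
    kernel = list(preset = "depth2.5", file = NULL),
    lq = list(alpha = 0.4337, beta = 0.0259, dt = NULL, form = "standard"),
    doses_Gy = c(2, 4, 6, 8),
    integration = list(n_points = 2000, replicates = 10, seed = 1,
                       combine_mode = "additive_excess"),
    mid_method = "closed_form")
}

#' Assemble and validate a pipeline configuration
#'
#' Builds the nested configuration consumed by \code{\link{run_pipeline}}.
#' Unknown keys (at the top level or inside a block) are rejected so that
#' misspelled options fail loudly; omitted keys take the documented
#' defaults. All physical quantities carry unit-suffixed names.
#'
#' @param ... named overrides, each a block (list) or scalar matching the
#'   default configuration structure (see \code{run_pipeline}).
#' @return Validated configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  if (length(over) && is.null(names(over)))
    stop("configuration overrides must be named")
  for (k in names(over)) {
    if (!k %in% names(cfg)) stop("unknown configuration key: ", k)
    if (is.list(cfg[[k]]) && is.list(over[[k]])) {
      bad <- setdiff(names(over[[k]]), names(cfg[[k]]))
      if (length(bad))
        stop(sprintf("unknown configuration key: %s$%s", k, bad[1]))
      cfg[[k]][names(over[[k]])] <- over[[k]]
    } else {
      cfg[[k]] <- over[[k]]
    }
  }
  # a user-specified load quantity supersedes the default count
  spec_keys <- c("count", "mass_per_cell_pg", "weight_percent")
  if ("load" %in% names(over)) {
    user_spec <- intersect(names(over$load), spec_keys)
    if (length(user_spec))
      for (k in setdiff(spec_keys, user_spec)) cfg$load[k] <- list(NULL)
  }
  ld <- cfg$load
  n_spec <- sum(!vapply(ld[spec_keys], is.null, logical(1)))
  if (n_spec != 1L)
    stop("load block must specify exactly one of count, mass_per_cell_pg, weight_percent")
  if (!cfg$placement$mode %in% c("homogeneous", "cytoplasm"))
    stop("unknown placement mode: ", cfg$placement$mode)
  if (!cfg$mid_method %in% c("closed_form", "quadrature", "trapezoid"))
    stop("unknown mid_method: ", cfg$mid_method)
  structure(cfg, class = "pipeline_config")
}

resolve_kernel <- function(kcfg) {
  if (!is.null(kcfg$file)) return(read_kernel(kcfg$file))
  gen_kernel(kernel_preset(kcfg$preset))
}

#' Run the full radiosensitization pipeline
#'
#' End to end: resolve the DER kernel (preset or file), convert the
#' nanoparticle load to a 2-D count, simulate the model survival curve under
#' the configured placement mode, fit the LQ model to it, compute mean
#' inactivation doses for the radiation-only response (the configured LQ
#' parameters) and the nanoparticle arm, and report the sensitization
#' enhancement ratio. Deterministic given the configuration: every
#' stochastic stage is seeded from \code{integration$seed}.
#'
#' Configuration blocks (see \code{\link{pipeline_config}} for validation):
#' \code{geometry} (ECM/cell/nucleus sizes, um), \code{load} (\code{count},
#' \code{mass_per_cell_pg} or \code{weight_percent}, plus
#' \code{np_diameter_nm} and \code{slice_fraction}), \code{placement}
#' (\code{mode}), \code{kernel} (\code{preset} or \code{file}), \code{lq}
#' (\code{alpha}, \code{beta}, optional \code{dt}, \code{form}),
#' \code{doses_Gy}, \code{integration} (\code{n_points}, \code{replicates},
#' \code{seed}, \code{combine_mode}), \code{mid_method}.
#'
#' @param config a \code{\link{pipeline_config}} (or plain list of
#'   overrides, which is validated first).
#' @return Report list: resolved \code{config}, \code{count}, \code{curve}
#'   (model survival curve), \code{fit} (LQ fit to the model curve),
#'   \code{mid_ir}, \code{mid_aunp}, \code{ser} (a \code{ser_result}), and
#'   \code{package_version}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  g <- config$geometry
  geometry <- cell_geometry(g$ecm_side_um, g$cell_diameter_um,
                            g$nucleus_diameter_um)
  ld <- config$load
  count <- load_to_count(count = ld$count,
                         mass_per_cell = ld$mass_per_cell_pg,
                         weight_percent = ld$weight_percent,
                         np_diameter = ld$np_diameter_nm,
                         geometry = geometry,
                         slice_fraction = ld$slice_fraction)
  kernel <- resolve_kernel(config$kernel)
  lq <- lq_parameters(config$lq$alpha, config$lq$beta, config$lq$dt)
  it <- config$integration
  curve <- model_survival_curve(
    geometry, count, config$placement$mode, kernel, lq,
    base_doses = config$doses_Gy, replicates = it$replicates,
    n_points = it$n_points, seed = it$seed,
    combine_mode = it$combine_mode, np_diameter = ld$np_diameter_nm,
    form = config$lq$form)
  fit <- fit_lq(curve)
  mm <- config$mid_method
  mid_ir <- if (mm == "trapezoid") {
    d <- config$doses_Gy
    mid(survival_curve(c(0, d), exp(local_log_survival(c(0, d), lq,
                                                       config$lq$form)),
                       source = "model"), "trapezoid")
  } else mid(lq, mm)
  mid_aunp <- if (mm == "trapezoid") mid(curve, "trapezoid") else mid(fit, mm)
  list(config = config, count = count, curve = curve, fit = fit,
       mid_ir = mid_ir, mid_aunp = mid_aunp,
       ser = ser(mid_ir, mid_aunp),
       package_version = as.character(utils::packageVersion("nanolem")))
}
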