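## Key-value configuration files in Debian-control (DCF) syntax: one block
## per record, blocks separated by blank lines. Records are typed by their
## `type` field: `model` (reference date, horizon), `nuclide` (one per
## nuclide: name, half_life_days, d0, decay_parent) and `parameterization`
## (a, slope_b, intercept_b). The dialect round-trips through
## write_model_config()/read_model_config().

#' Write a model configuration file
#'
#' Serializes a [beta_dose_model()] (nuclide half-lives and calibrated
#' coefficients plus the linear parameterization) to a plain-text key-value
#' file.
#'
#' @param model A `"beta_dose_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "beta_dose_model"))
  ns <- model$nuclides
  blocks <- c(
    list(data.frame(type = "model",
                    reference_date = format(attr(ns, "reference_date")),
                    horizon_hours = model$horizon_hours,
                    te_split = model$te_split, cs_split = model$cs_split)),
    list(data.frame(type = "parameterization",
                    a = sprintf("%.12g", model$param$a),
                    slope_b = sprintf("%.12g", model$param$slope_b),
                    intercept_b = sprintf("%.12g", model$param$intercept_b))),
    lapply(seq_len(nrow(ns)), function(i)
      data.frame(type = "nuclide", name = ns$name[i],
                 half_life_days = sprintf("%.12g", ns$half_life_hours[i] / 24),
                 d0 = sprintf("%.12g", ns$d0[i]),
                 decay_parent = ifelse(is.na(ns$decay_parent[i]), "none",
                                       ns$decay_parent[i]))))
  con <- file(path, "w")
  on.exit(close(con))
  for (b in blocks) {
    write.dcf(b, con)
    cat("\n", file = con)
  }
  invisible(path)
}

#' Read a model configuration file
#'
#' Reads the key-value dialect written by [write_model_config()] and
#' rebuilds the model. If the nuclide blocks carry all-zero `d0`, the model
#' is re-calibrated from the parameterization block (which is then
#' required).
#'
#' @param path Configuration file.
#' @return A `"beta_dose_model"`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  if (is.null(d$type)) stop("invalid config: records lack a 'type' field")
  bad <- setdiff(unique(d$type), c("model", "parameterization", "nuclide"))
  if (length(bad)) stop("invalid config key: unknown record type '", bad[1], "'")
  meta <- d[d$type == "model", , drop = FALSE]
  par <- d[d$type == "parameterization", , drop = FALSE]
  nuc <- d[d$type == "nuclide", , drop = FALSE]
  if (nrow(nuc) != 7) stop("config must define exactly seven nuclides")
  hl <- stats::setNames(as.numeric(nuc$half_life_days), nuc$name)
  d0 <- stats::setNames(as.numeric(nuc$d0), nuc$name)
  parent_raw <- stats::setNames(nuc$decay_parent, nuc$name)
  parent_raw <- parent_raw[!is.na(parent_raw) & parent_raw != "none"]
  ref <- if (nrow(meta)) as.Date(meta$reference_date[1]) else
    as.Date("2011-03-15")
  horizon <- if (nrow(meta)) as.numeric(meta$horizon_hours[1]) else
    hours_per_year()
  te_split <- if (nrow(meta) && !is.null(meta$te_split))
    as.numeric(meta$te_split[1]) else 0.5
  cs_split <- if (nrow(meta) && !is.null(meta$cs_split))
    as.numeric(meta$cs_split[1]) else 0.5
  ns <- nuclide_set(hl, d0 = d0, decay_parent = parent_raw,
                    reference_date = ref)
  if (!nrow(par)) stop("config lacks a parameterization record")
  p <- parameterization(as.numeric(par$a[1]), as.numeric(par$slope_b[1]),
                        as.numeric(par$intercept_b[1]))
  if (all(ns$d0 == 0)) {
    beta_dose_model(p, ns, te_split, cs_split, horizon)
  } else {
    structure(list(nuclides = ns, param = p, horizon_hours = horizon,
                   te_split = te_split, cs_split = cs_split),
              class = "beta_dose_model")
  }
}
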