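CONFIG_SCHEMA_VERSION <- 1L

config_top_keys <- c("schema_version", "label", "currency", "arms", "econ",
                     "settings", "wtp", "se")
config_arm_keys <- c("name", "p_hhf", "p_cvd", "p_ncd", "drug_cost")
config_econ_keys <- c("u_stable", "u_age_decrement", "u_hhf_decrement",
                      "cost_stable", "cost_hhf", "cost_pre_cvd",
                      "cost_pre_ncd", "discount_rate_annual")
config_settings_keys <- c("start_age", "horizon_cycles", "cycle_length_months",
                          "first_cycle_event_free", "half_cycle_correction",
                          "accrual_months", "discount_method", "age_step")

check_keys <- function(x, allowed, required, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("config: unknown key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("config: missing required key(s) in ", where, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Load a country setting from a config file
#'
#' Reads a UTF-8 YAML configuration (schema version 1; see the bundled
#' `taiwan_base.yaml` for the documented layout: top-level `label`,
#' `currency`, nested `arms` (exactly `intervention` and `comparator`),
#' `econ`, `settings`, `wtp` and an optional `se` block of standard errors).
#' All type invariants are enforced on load; unknown keys are rejected with an
#' error naming the offending key. Currency is always US$ and probabilities
#' are always monthly.
#'
#' @param path Path to the config file.
#' @return A validated [country_setting()].
#' @examples
#' cfg <- system.file("extdata", "taiwan_base.yaml", package = "hfcea")
#' load_setting(cfg)
#' @export
load_setting <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys(raw, config_top_keys,
             c("schema_version", "label", "arms", "econ", "wtp"), "top level")
  if (raw$schema_version != CONFIG_SCHEMA_VERSION)
    stop("config: unsupported schema_version ", raw$schema_version, call. = FALSE)
  if (!is.null(raw$currency) && raw$currency != "USD")
    stop("config: currency must be USD", call. = FALSE)
  check_keys(raw$arms, c("intervention", "comparator"),
             c("intervention", "comparator"), "arms")
  arms <- lapply(c("intervention", "comparator"), function(a) {
    check_keys(raw$arms[[a]], config_arm_keys, config_arm_keys,
               paste0("arms.", a))
    do.call(arm_parameters, raw$arms[[a]])
  })
  check_keys(raw$econ, config_econ_keys, config_econ_keys, "econ")
  econ <- do.call(economic_inputs, raw$econ)
  settings <- if (is.null(raw$settings)) model_settings() else {
    check_keys(raw$settings, config_settings_keys, character(0), "settings")
    do.call(model_settings, raw$settings)
  }
  check_keys(raw$wtp, c("wtp_1x", "wtp_3x"), c("wtp_1x", "wtp_3x"), "wtp")
  se <- raw$se
  if (!is.null(se)) {
    check_keys(se, c("intervention", "comparator", "econ"), character(0), "se")
    for (a in intersect(c("intervention", "comparator"), names(se)))
      check_keys(se[[a]], setdiff(config_arm_keys, "name"), character(0),
                 paste0("se.", a))
    if (!is.null(se$econ))
      check_keys(se$econ, config_econ_keys, character(0), "se.econ")
  }
  country_setting(raw$label, arms[[1]], arms[[2]], econ, settings,
                  as.numeric(raw$wtp$wtp_1x), as.numeric(raw$wtp$wtp_3x), se)
}

#' Save a country setting to a config file
#'
#' Writes the schema-version-1 YAML representation read by [load_setting()];
#' `load_setting(save_setting(x, path))` reproduces `x` field for field.
#'
#' @param setting A [country_setting()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_setting <- function(setting, path) {
  stopifnot(inherits(setting, "country_setting"))
  obj <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    label = setting$label,
    currency = "USD",
    arms = list(intervention = unclass(setting$intervention),
                comparator = unclass(setting$comparator)),
    econ = unclass(setting$econ),
    settings = unclass(setting$settings),
    wtp = list(wtp_1x = setting$wtp_1x, wtp_3x = setting$wtp_3x)
  )
  if (!is.null(setting$se)) obj$se <- setting$se
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Flatten a country setting for audit export
#'
#' @param x A [country_setting()].
#' @param ... Unused.
#' @param stringsAsFactors Unused (base generic compatibility).
#' @return A data frame with columns `parameter` (dotted path) and `value`,
#'   one row per scalar parameter; suitable for `write.csv`.
#' @export
as.data.frame.country_setting <- function(x, ..., stringsAsFactors = FALSE) {
  rows <- list(data.frame(parameter = "label", value = x$label),
               data.frame(parameter = "wtp.wtp_1x", value = format(x$wtp_1x)),
               data.frame(parameter = "wtp.wtp_3x", value = format(x$wtp_3x)))
  for (section in c("intervention", "comparator", "econ", "settings")) {
    v <- unclass(x[[section]])
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0(section, ".", names(v)),
      value = vapply(v, function(z) format(z, digits = 15), character(1))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
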