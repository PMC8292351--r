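# Dataset CSV schema and YAML run configuration.

dataset_columns <- c("time_s", "record_type", "Q", "T_leaf", "C_a",
                     "O_mbar", "P_bar", "A", "E_mmol", "g_tc", "F_s",
                     "F_m_or_Fm_prime", "F_o_or_Fo_prime")

#' Write a dataset to CSV
#'
#' One row per observation in the standard column layout; dark rows carry
#' `F_m`/`F_o` in the shared fluorescence columns, light rows `F_m'`/`F_o'`.
#'
#' @param dataset A `pam_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  missing_cols <- setdiff(dataset_columns, names(dataset))
  if (length(missing_cols))
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.csv(dataset[dataset_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset CSV
#'
#' Validates the column layout, record types and timestamp ordering.
#'
#' @param path CSV path.
#' @return A `pam_dataset` data.frame.
#' @export
read_dataset_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(dataset_columns, names(d))
  if (length(missing_cols))
    stop("malformed dataset: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!d$record_type %in% c("dark", "light"))
  if (length(bad))
    stop("malformed record_type in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (is.unsorted(d$time_s)) stop("timestamps must be non-decreasing")
  if (!any(d$record_type == "dark"))
    stop("dataset needs at least one dark record for F_m/F_o")
  class(d) <- c("pam_dataset", class(d))
  d
}

#' Read a YAML run configuration
#'
#' Sections `env`, `leaf`, `photochemical_constants`,
#' `biochemical_constants`, `detector` keyed by the parameter names of the
#' corresponding constructors; omitted sections and keys fall back to the
#' package defaults. Unknown keys are rejected with their section path.
#'
#' @param path YAML file path; `NULL` gives the all-defaults configuration.
#' @return List with `env`, `leaf`, `k`, `kin`, `coupling`, `detector`.
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- list(
    env = c("Q", "T_leaf", "C", "O", "P"),
    leaf = c("alpha_total", "alpha_1", "alpha_2", "V_max_cb6f",
             "V_max_rubc", "R_d", "g_m", "state_transitions", "cef_mode",
             "npq_mode", "b6f_control", "k_q"),
    photochemical_constants = c("K_P1", "K_D1", "K_F1", "K_X1", "K_P2",
                                "K_D2", "K_F2", "K_U2"),
    biochemical_constants = c("k_c", "K_c", "k_o", "K_o", "q_cycle_on",
                              "ndh_pump_on", "h_per_atp"),
    detector = c("S_det", "eps_F2", "eps_F1")
  )
  for (sec in names(cfg)) {
    if (!sec %in% names(known))
      stop("unknown config section: ", sec)
    extra <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(extra))
      stop("unknown key(s) in section '", sec, "': ",
           paste(extra, collapse = ", "))
  }
  bio <- cfg$biochemical_constants
  kin_keys <- intersect(names(bio), c("k_c", "K_c", "k_o", "K_o"))
  sc_keys <- intersect(names(bio), c("q_cycle_on", "ndh_pump_on",
                                     "h_per_atp"))
  list(
    env = do.call(leaf_env, cfg$env %||% list()),
    leaf = do.call(leaf_parameters, cfg$leaf %||% list()),
    k = do.call(photo_constants, cfg$photochemical_constants %||% list()),
    kin = do.call(rubisco_kinetics, bio[kin_keys] %||% list()),
    coupling = coupling_efficiencies(
      do.call(coupling_scenario, bio[sc_keys] %||% list())),
    detector = do.call(detector_model, cfg$detector %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
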