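# Readers and writers for trace files, relaxation profiles, equilibrium
# curves, manifests and parameter reports.  All tabular formats are plain
# comma-delimited text with `# key=value` metadata headers.

.read_header_meta <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_0-9]+)\\s*=\\s*(.*)$", hdr))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- as.numeric(m[3])
  out
}

#' Write a stopped-flow trace file
#'
#' Format: comment header `# ligand_uM=`, `# temp_K=`, `# dead_time_s=`,
#' then a `time_s,signal` CSV table.
#'
#' @param trace an [sf_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sf_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# ligand_uM=%.10g", trace$ligand_uM),
               sprintf("# temp_K=%.10g", trace$temp_K),
               sprintf("# dead_time_s=%.10g", trace$dead_time_s),
               "time_s,signal"), con)
  utils::write.table(data.frame(format(trace$time, digits = 15),
                                format(trace$signal, digits = 15)),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a stopped-flow trace file
#'
#' @param path file written by [write_trace()].
#' @return an [sf_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta <- .read_header_meta(lines)
  need <- c("ligand_uM", "temp_K", "dead_time_s")
  if (!all(need %in% names(meta)))
    stop("trace file ", path, " is missing header metadata", call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = body)
  sf_trace(tab$time_s, tab$signal, ligand_uM = meta$ligand_uM,
           temp_K = meta$temp_K, dead_time_s = meta$dead_time_s)
}

#' Write a relaxation profile table
#' @param profile data.frame from [extract_relaxation_profile()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a relaxation profile table
#' @param path CSV written by [write_profile()].
#' @return data.frame.
#' @export
read_profile <- function(path) {
  utils::read.csv(path, colClasses = c(
    ligand_uM = "numeric", temp_K = "numeric", alpha1_s = "numeric",
    alpha2_s = "numeric", a1 = "numeric", a2 = "numeric",
    n_exp = "integer"))
}

#' Read an equilibrium curve file
#'
#' Two-column CSV (`den_M,signal` or `na_mM,signal`) with an optional
#' `# temp_K=` header.
#'
#' @param path file path.
#' @return data.frame with a `temp_K` attribute when present.
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  meta <- .read_header_meta(lines)
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!is.null(meta$temp_K)) attr(tab, "temp_K") <- meta$temp_K
  tab
}

#' Write an equilibrium curve file
#' @param curve data.frame with two columns (concentration, signal).
#' @param path output path.
#' @param temp_K optional temperature recorded in the header.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, temp_K = attr(curve, "temp_K")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(temp_K)) writeLines(sprintf("# temp_K=%.10g", temp_K), con)
  utils::write.csv(curve, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# JSON-able description of a global model (laws + diagnostics summary).
.model_to_list <- function(model) {
  list(kind = model$kind, T0 = model$T0,
       laws = lapply(model$laws, function(l) list(k0 = l$k0, E = l$E)),
       diagnostics = if (is.null(model$diagnostics)) NULL else
         list(rss = model$diagnostics$rss, dof = model$diagnostics$dof,
              se = as.list(model$diagnostics$se),
              converged = model$diagnostics$converged))
}

.model_from_list <- function(x) {
  laws <- lapply(x$laws, function(l) arrhenius_law(l$k0, l$E, x$T0))
  m <- global_kinetic_model(x$kind, laws)
  m$diagnostics <- x$diagnostics
  m
}

#' Write a global kinetic model to JSON
#' @param model a [global_kinetic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(.model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a global kinetic model from JSON
#' @param path JSON written by [write_model_json()].
#' @return a [global_kinetic_model()].
#' @export
read_model_json <- function(path) {
  .model_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Kinetic/thermodynamic report for fitted variants
#'
#' One row per fitted model: rate constants and activation energies at T0
#' plus the derived thermodynamics at T0 — the shape of a published
#' rate-constant table.
#'
#' @param models named list of [global_kinetic_model()] objects.
#' @param T evaluation temperature for the thermodynamics (default: T0 of
#'   each model).
#' @return data.frame with columns `variant`, `koff0_s`, `kon0_uMs`,
#'   `Eoff_kcal`, `Eon_kcal`, `Kd_uM`, `dG_kcal`, `dH_kcal`, `dS_cal`.
#' @export
thermo_report <- function(models, T = NULL) {
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    th <- derive_thermo(m, if (is.null(T)) m$T0 else T)
    data.frame(variant = nm,
               koff0_s = m$laws$koff$k0, kon0_uMs = m$laws$kon$k0,
               Eoff_kcal = m$laws$koff$E, Eon_kcal = m$laws$kon$E,
               Kd_uM = th$Kd_uM, dG_kcal = th$dG_kcal,
               dH_kcal = th$dH_kcal, dS_cal = th$dS_cal)
  })
  do.call(rbind, rows)
}

# Small stable FNV-1a hash of a config (for run logs); avoids a digest
# dependency.
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
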