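#' Read a tidy circadian expression CSV
#'
#' Expected columns: `label`, `zt` (h in \[0,24)), `replicate_id`,
#' `value`.  One [timed_replicates] object is returned per label.
#'
#' @param path CSV file path.
#' @return Named list of [timed_replicates].
#' @export
read_expression_csv <- function(path) {
  df <- read_checked_csv(path, c("label", "zt", "replicate_id", "value"))
  check_numeric_col(df, "zt", path); check_numeric_col(df, "value", path)
  bad <- which(df$zt < 0 | df$zt >= 24)
  if (length(bad))
    stop(path, ": zt out of [0, 24) at row(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  out <- lapply(split(df, df$label), function(g) {
    zts <- sort(unique(g$zt))
    timed_replicates(zts,
                     lapply(zts, function(z) g$value[g$zt == z]),
                     label = g$label[1])
  })
  out
}

#' Write timed replicates to the tidy expression CSV dialect
#'
#' @param data a [timed_replicates] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(data, path) {
  if (inherits(data, "timed_replicates")) data <- list(data)
  rows <- do.call(rbind, lapply(data, function(tr) {
    do.call(rbind, lapply(seq_along(tr$zt_hours), function(i) {
      v <- tr$values_per_zt[[i]]
      data.frame(label = tr$label, zt = tr$zt_hours[i],
                 replicate_id = seq_along(v), value = v)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy PK CSV into grouped datasets
#'
#' Expected columns: `sex`, `feeding`, `zt_dose`, `t_h`, `mouse_id`,
#' `matrix` (plasma/ileum/liver), `concentration`.  Mice are linked
#' across matrices by `mouse_id` within each group and time point.
#'
#' @param path CSV file path.
#' @return Named list of [pk_group_dataset] (name: sex_feeding_ZT).
#' @export
read_pk_csv <- function(path) {
  df <- read_checked_csv(path, c("sex", "feeding", "zt_dose", "t_h",
                                 "mouse_id", "matrix", "concentration"))
  check_numeric_col(df, "t_h", path)
  check_numeric_col(df, "concentration", path)
  check_numeric_col(df, "zt_dose", path)
  if (!all(df$matrix %in% c("plasma", "ileum", "liver")))
    stop(path, ": matrix must be plasma, ileum or liver")
  key <- paste(df$sex, df$feeding, paste0("ZT", df$zt_dose), sep = "_")
  lapply(split(df, key), function(g) {
    times <- sort(unique(g$t_h))
    conc <- lapply(c(plasma = "plasma", ileum = "ileum", liver = "liver"),
                   function(m) {
      lapply(times, function(tt) {
        sub <- g[g$matrix == m & g$t_h == tt, ]
        sub$concentration[order(sub$mouse_id)]
      })
    })
    pk_group_dataset(g$sex[1], g$feeding[1], g$zt_dose[1], conc,
                     times = times)
  })
}

#' Write grouped PK datasets to the tidy PK CSV dialect
#'
#' @param groups a [pk_group_dataset] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_csv <- function(groups, path) {
  if (inherits(groups, "pk_group_dataset")) groups <- list(groups)
  rows <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(seq_along(g$times), function(j) {
      do.call(rbind, lapply(c("plasma", "ileum", "liver"), function(m) {
        v <- g$conc[[m]][[j]]
        data.frame(sex = g$sex, feeding = g$feeding, zt_dose = g$zt_dose,
                   t_h = g$times[j], mouse_id = seq_along(v), matrix = m,
                   concentration = v)
      }))
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a bioluminescence CSV
#'
#' Expected columns: `series_id` (optional), `t_h`, `counts`.
#'
#' @param path CSV file path.
#' @return data.frame with `series_id`, `t_h`, `counts`.
#' @export
read_biolum_csv <- function(path) {
  df <- read_checked_csv(path, c("t_h", "counts"))
  check_numeric_col(df, "t_h", path); check_numeric_col(df, "counts", path)
  if (is.null(df$series_id)) df$series_id <- "series1"
  df[, c("series_id", "t_h", "counts")]
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(path, ": unreadable CSV (",
                                          conditionMessage(e), ")"))
  if (nrow(df) == 0) stop(path, ": no data rows")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  df
}

check_numeric_col <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (length(bad))
    stop(path, ": non-numeric '", col, "' at row(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  if (anyNA(v)) stop(path, ": missing '", col, "' values")
  df[[col]] <- v
  invisible(TRUE)
}

#' Write a cosinor fit as a JSON record
#'
#' @param fit a `cosinor_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_cosinor_json <- function(fit, path) {
  stopifnot(inherits(fit, "cosinor_fit"))
  rec <- list(label = fit$label, mesor = fit$mesor,
              residual_ss = fit$residual_ss, n_obs = fit$n_obs,
              components = fit$components)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize model parameters to YAML
#'
#' @param p a [pbpk_parameters].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_pbpk_yaml <- function(p, path) {
  stopifnot(inherits(p, "pbpk_parameters"))
  as_list <- function(r) list(mean_rate = r$mean_rate,
                              rel_amplitudes = r$rel_amplitudes,
                              periods = r$periods,
                              acrophases = r$acrophases)
  yaml::write_yaml(list(
    ka = p$ka, k_ib = p$k_ib, k_pl_li = p$k_pl_li, k_li_pl = p$k_li_pl,
    pgp_ileum = as_list(p$pgp_ileum), pgp_liver = as_list(p$pgp_liver),
    renal = as_list(p$renal), intestinal = as_list(p$intestinal),
    body_weight_g = p$body_weight_g, V_plasma_mL = p$V_plasma_mL,
    W_ileum_g = p$W_ileum_g, W_liver_g = p$W_liver_g), path)
  invisible(path)
}

#' Read model parameters from YAML
#'
#' @param path YAML path written by [write_pbpk_yaml].
#' @return A [pbpk_parameters] object.
#' @export
read_pbpk_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  as_rate <- function(l) circadian_rate(l$mean_rate,
                                        as.numeric(l$rel_amplitudes %||% numeric()),
                                        as.numeric(l$periods %||% numeric()),
                                        as.numeric(l$acrophases %||% numeric()))
  pbpk_parameters(y$ka, y$k_ib, y$k_pl_li, y$k_li_pl,
                  pgp_ileum = as_rate(y$pgp_ileum),
                  pgp_liver = as_rate(y$pgp_liver),
                  renal = as_rate(y$renal),
                  intestinal = as_rate(y$intestinal),
                  body_weight_g = y$body_weight_g,
                  V_plasma_mL = y$V_plasma_mL,
                  W_ileum_g = y$W_ileum_g, W_liver_g = y$W_liver_g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a simulation as tidy CSV
#'
#' @param s a `pbpk_sim`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(s, path) {
  stopifnot(inherits(s, "pbpk_sim"))
  comp <- colnames(s$amounts)
  rows <- do.call(rbind, lapply(comp, function(cmp) {
    cc <- switch(cmp, plasma = s$concentrations[, "plasma"],
                 ileum = s$concentrations[, "ileum"],
                 liver = s$concentrations[, "liver"],
                 rep(NA_real_, length(s$t)))
    data.frame(t_h = s$t, compartment = cmp, amount_ug = s$amounts[, cmp],
               concentration = cc)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
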