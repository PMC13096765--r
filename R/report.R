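#' Fit, diagnose, and report in one call
#'
#' Runs the full diagnostic workflow on a prepared dataset: fits the
#' multistate Cox model, computes the requested local-influence schemes and
#' (optionally) the case-deletion measures, and writes tab-separated tables
#' plus index-plot data to a directory. Outputs are deterministic given the
#' same inputs: a rerun reproduces byte-identical tables.
#'
#' Files written: \code{fit.tsv} (coefficient table), \code{baseline.tsv}
#' (per-transition Nelson-Aalen cumulative hazards),
#' \code{scheme_<s>.tsv} (label, Bi, abs_hmax, cutoff, flag per component),
#' \code{indexplot_scheme_I.tsv} (per-transition panel data: trans, index
#' within transition, id, Bi), \code{global.tsv} (per-patient Cook distance
#' and likelihood displacement), and \code{summary.tsv} (flag counts per
#' scheme, and per transition for Scheme I).
#'
#' @param data an \code{"msdata"} with an expanded design.
#' @param out_dir output directory (created if missing).
#' @param schemes subset of \code{c("I", "II", "III")}; may be empty if
#'   \code{global} is \code{TRUE}.
#' @param global also compute case-deletion (global) diagnostics.
#' @param exact pass exact deletion refits through to [global_influence()].
#' @return (invisibly) list with \code{fit}, \code{local} (named list of
#'   \code{"ms_curvature"}), \code{global}, and \code{files}.
#' @export
run_diagnose <- function(data, out_dir, schemes = c("I", "II", "III"),
                         global = TRUE, exact = FALSE) {
  if (!length(schemes) && !global)
    stop("nothing to do: no schemes selected and global = FALSE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- fit_mscox(data)
  files <- character(0)
  s <- summary(fit)$coefficients
  files["fit"] <- write_tsv(cbind(term = rownames(s), s),
                            file.path(out_dir, "fit.tsv"))
  bl <- do.call(rbind, lapply(seq_along(fit$baseline), function(g)
    if (nrow(fit$baseline[[g]]))
      cbind(trans = g, fit$baseline[[g]])))
  files["baseline"] <- write_tsv(bl, file.path(out_dir, "baseline.tsv"))
  local <- if (length(schemes)) local_influence(fit, data, schemes) else list()
  for (s_name in names(local)) {
    cv <- local[[s_name]]
    tab <- data.frame(label = names(cv$Bi), Bi = cv$Bi,
                      abs_hmax = abs(cv$hmax), cutoff = cv$cutoff,
                      flag = names(cv$Bi) %in% cv$flagged)
    files[paste0("scheme_", s_name)] <-
      write_tsv(tab, file.path(out_dir, paste0("scheme_", s_name, ".tsv")))
  }
  if ("I" %in% names(local)) {
    rec <- data$records
    ord <- scheme1_column_order(data)
    ip <- data.frame(trans = rec$trans[ord],
                     index = stats::ave(rec$trans[ord], rec$trans[ord],
                                        FUN = seq_along),
                     id = rec$id[ord],
                     Bi = unname(local[["I"]]$Bi))
    files["indexplot_I"] <- write_tsv(ip,
                                      file.path(out_dir,
                                                "indexplot_scheme_I.tsv"))
  }
  glob <- NULL
  if (global) {
    glob <- global_influence(fit, data, exact = exact)
    files["global"] <- write_tsv(as.data.frame(glob),
                                 file.path(out_dir, "global.tsv"))
  }
  sumtab <- data.frame(measure = character(0), flagged = integer(0))
  for (s_name in names(local))
    sumtab <- rbind(sumtab, data.frame(
      measure = paste0("scheme_", s_name),
      flagged = length(local[[s_name]]$flagged)))
  if ("I" %in% names(local)) {
    fl <- local[["I"]]$flagged
    g_of <- sub("^g([0-9]+):.*$", "\\1", fl)
    for (g in seq_len(n_transitions(data$graph)))
      sumtab <- rbind(sumtab, data.frame(
        measure = paste0("scheme_I_trans_", g),
        flagged = sum(g_of == as.character(g))))
  }
  if (!is.null(glob))
    sumtab <- rbind(sumtab, data.frame(measure = "global_cook",
                                       flagged = sum(glob$flag)))
  files["summary"] <- write_tsv(sumtab, file.path(out_dir, "summary.tsv"))
  invisible(list(fit = fit, local = local, global = glob, files = files))
}

#' Compare the full fit with a fit excluding flagged patients
#'
#' Refits the model without the given patients and reports coefficients,
#' standard errors, and two-sided Wald p-values side by side. With an empty
#' removal set the two halves of the table are identical.
#'
#' @param data an \code{"msdata"} with an expanded design.
#' @param remove_ids patient ids to drop before refitting (e.g. the flagged
#'   labels of a Scheme III analysis).
#' @param out path to write the tab-separated table to, or \code{NULL}.
#' @return data.frame with columns \code{term}, \code{coef_full},
#'   \code{se_full}, \code{p_full}, \code{coef_reduced}, \code{se_reduced},
#'   \code{p_reduced}.
#' @export
run_compare <- function(data, remove_ids = character(0), out = NULL) {
  full <- fit_mscox(data)
  red <- if (length(remove_ids)) fit_mscox(drop_patients(data, remove_ids),
                                           init = full$beta)
         else full
  wald <- function(f) {
    se <- sqrt(diag(f$V))
    data.frame(coef = f$beta, se = se, p = 2 * stats::pnorm(-abs(f$beta / se)))
  }
  a <- wald(full); b <- wald(red)
  tab <- data.frame(term = names(full$beta),
                    coef_full = a$coef, se_full = a$se, p_full = a$p,
                    coef_reduced = b$coef, se_reduced = b$se,
                    p_reduced = b$p, row.names = NULL)
  if (!is.null(out)) write_tsv(tab, out)
  tab
}

# Deterministic full-precision TSV writer (internal).
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.15g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
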