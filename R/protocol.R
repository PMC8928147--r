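#' Render a standardized univariate power-analysis protocol
#'
#' Produces the fixed-layout text block recommended for reporting sample-size
#' calculations in full (the layout mirrors the protocol emitted by common
#' power-analysis software): an Options/Analysis/Input/Output structure in
#' which every input is echoed verbatim and the Output block carries the
#' noncentrality parameter, critical value, degrees of freedom, solved sample
#' sizes and the actual (achieved) power.
#'
#' @param solution a `"power_solution"` from [sample_size()] (a priori) or
#'   [power_posthoc()] (post hoc).
#' @param metric optional alpha-metric name echoed in the Input block.
#' @return character vector of class `"power_protocol"` (one line per entry)
#'   with a `"record"` attribute holding the machine-readable fields.
#' @export
render_protocol_univariate <- function(solution, metric = NULL) {
  stopifnot(inherits(solution, "power_solution"))
  spec <- solution$spec
  fmt <- function(x) format(x, digits = 15)
  head_line <- switch(spec$test,
    wmw = "t-tests - Means: Wilcoxon-Mann-Whitney test (two groups)",
    t_test = "t-tests - Means: Difference between two independent means (two groups)",
    anova = "F-tests - ANOVA: Fixed effects, omnibus, one-way")
  a_priori <- solution$kind == "a_priori"
  lines <- c(
    "Power analysis protocol: univariate case - alpha diversity",
    head_line)
  if (spec$test == "wmw") lines <- c(lines, "Options:   A.R.E. method")
  lines <- c(lines, paste0("Analysis:  ",
                           if (a_priori) "A priori: compute required sample size"
                           else "Post hoc: compute achieved power"))
  inp <- character(0)
  if (spec$test != "anova")
    inp <- c(inp, c("Tail(s)" = switch(spec$tails, one = "One", two = "Two")))
  if (spec$test == "wmw")
    inp <- c(inp, c("Parent distribution" = switch(spec$parent, normal = "Normal",
                                                   min = "Minimum A.R.E.")))
  inp <- c(inp,
           setNames(fmt(spec$effect),
                    if (spec$test == "anova") "Effect size f" else "Effect size d"))
  if (!is.null(metric)) inp <- c(inp, c("Alpha metric" = metric))
  inp <- c(inp, c("alpha err prob" = fmt(spec$alpha_level)))
  if (spec$test == "anova")
    inp <- c(inp, c("Number of groups" = fmt(spec$groups)))
  if (a_priori) {
    inp <- c(inp, c("Power (1-beta err prob)" = fmt(solution$target_power)))
    if (spec$test != "anova")
      inp <- c(inp, c("Allocation ratio N2/N1" = fmt(spec$allocation_ratio)))
  } else {
    inp <- c(inp, c("Sample size group 1" = fmt(solution$n1),
                    "Sample size group 2" = fmt(solution$n2)))
  }
  out <- c(setNames(sprintf("%.4f", solution$noncentrality),
                    if (spec$test == "anova") "Noncentrality parameter lambda"
                    else "Noncentrality parameter delta"),
           setNames(sprintf("%.4f", solution$critical_value),
                    if (spec$test == "anova") "Critical F" else "Critical t"),
           c("df" = paste(sprintf("%.4f", solution$df), collapse = ", ")))
  if (a_priori)
    out <- c(out, c("Sample size group 1" = fmt(solution$n1),
                    "Sample size group 2" = fmt(solution$n2),
                    "Total sample size" = fmt(solution$n_total),
                    "Actual power" = sprintf("%.3f", solution$achieved_power)))
  else
    out <- c(out, c("Achieved power" = sprintf("%.4f", solution$achieved_power)))
  lines <- c(lines, "Input:", paste0("  ", format(names(inp), width = 32), " = ", inp),
             "Output:", paste0("  ", format(names(out), width = 32), " = ", out))
  structure(lines, class = "power_protocol",
            record = list(kind = solution$kind, test = spec$test,
                          input = as.list(inp), output = as.list(out)))
}

#' Render a standardized multivariate (PERMANOVA) power protocol
#'
#' Reports the achievable power of a PERMANOVA comparison at one per-group
#' size of an empirical-power run, together with the observed effect sizes
#' (average and min/max of omega-squared and Cohen's f across the run's
#' iterations) — the information a reader needs to reuse the run as pilot
#' data.
#'
#' @param curve a `power_curve` from [empirical_power_beta()] run with
#'   `keep_effects = TRUE`.
#' @param scheme the [subsample_scheme()] used for the run.
#' @param n per-group size to report (must be on the curve's grid); defaults
#'   to the smallest grid size.
#' @return character vector of class `"power_protocol"` with a `"record"`
#'   attribute.
#' @export
render_protocol_multivariate <- function(curve, scheme, n = curve$n[1L]) {
  effects <- attr(curve, "effects")
  if (is.null(effects)) stop("curve carries no per-iteration effects; rerun with keep_effects = TRUE")
  row <- match(n, curve$n)
  if (is.na(row)) stop("n = ", n, " is not on the curve's grid")
  eff <- effects[[as.character(n)]]
  if (is.null(eff) || !nrow(eff)) stop("no iterations recorded at n = ", n)
  f_obs <- sqrt(eff$cohens_f2)
  fmt <- function(x) sprintf("%.6f", x)
  inp <- c("Beta metric" = curve$metric[row],
           "alpha err prob" = format(attr(curve, "alpha_level"), digits = 15),
           "Number of groups" = "2",
           "Number of taxa" = format(attr(curve, "n_taxa")),
           "Sample size group 1" = format(n),
           "Sample size group 2" = format(n))
  out <- c("Observed effect size (average) omega2" = fmt(mean(eff$omega_squared)),
           "Min\\Max effect size" = paste0(fmt(min(eff$omega_squared)), "\\",
                                           fmt(max(eff$omega_squared))),
           "Observed effect size (average) f" = fmt(mean(f_obs)),
           "Min\\Max effect size f" = paste0(fmt(min(f_obs)), "\\", fmt(max(f_obs))),
           "Numerator df" = "1",
           "Denominator df" = format(2L * n - 2L),
           "Power (1-beta err prob)" = sprintf("%.4f", curve$power[row]))
  lines <- c("Power analysis protocol: multivariate case - beta diversity",
             "Test - PERMANOVA",
             paste0("Options:   ", format(attr(curve, "n_permutations")), " permutations"),
             paste0("           ", curve$K[row], " iterations"),
             "Analysis:  Compute achievable power",
             "Input:", paste0("  ", format(names(inp), width = 38), " = ", inp),
             "Output:", paste0("  ", format(names(out), width = 38), " = ", out))
  structure(lines, class = "power_protocol",
            record = list(kind = "achievable", test = "permanova",
                          input = as.list(inp), output = as.list(out)))
}

#' Parse a rendered protocol back into its fields
#'
#' Recovers every `name = value` line of a rendered protocol, keyed by the
#' (trimmed) field name — the inverse of the renderers for the Input/Output
#' blocks, used to verify that protocols are self-describing.
#'
#' @param protocol a `"power_protocol"` character vector (or plain lines).
#' @return list with `input` and `output` named lists of character values.
#' @export
parse_protocol <- function(protocol) {
  lines <- as.character(protocol)
  section <- NA_character_
  input <- list()
  output <- list()
  for (ln in lines) {
    if (grepl("^Input:", ln)) { section <- "input"; next }
    if (grepl("^Output:", ln)) { section <- "output"; next }
    if (is.na(section) || !grepl(" = ", ln, fixed = TRUE)) next
    parts <- strsplit(ln, " = ", fixed = TRUE)[[1L]]
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = " = "))
    if (section == "input") input[[key]] <- val else output[[key]] <- val
  }
  list(input = input, output = output)
}

#' @export
print.power_protocol <- function(x, ...) {
  cat(paste(x, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a protocol with its machine-readable JSON twin
#'
#' Writes the human-readable text to `path` and the structured record to
#' `paste0(path, ".json")`.
#'
#' @param protocol a `"power_protocol"`.
#' @param path output text file.
#' @return invisibly, the two paths written.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "power_protocol"))
  writeLines(as.character(protocol), path)
  json_path <- paste0(path, ".json")
  jsonlite::write_json(attr(protocol, "record"), json_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(path, json_path))
}
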