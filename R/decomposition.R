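# Component-energy tables, composition identities, consistency checks, and
# the WCA split of the Lennard-Jones potential.

# canonical column order of the delimited-text schema
.component_cols <- c("name", "dA_hyd", "e_reorg", "dA_es", "dA_disp", "dA_cav")
.optional_cols <- c("exp_dA_hyd", "asa")

#' Build a solute component table
#'
#' One row per solute with the four energy components of the hydration
#' free-energy decomposition (all kcal/mol): reorganization energy `e_reorg`,
#' electrostatic `dA_es`, dispersion `dA_disp`, cavitation `dA_cav`; plus an
#' optional printed total `dA_hyd`, an optional experimental reference
#' `exp_dA_hyd`, and an optional solvent-accessible surface area `asa`
#' (Angstrom^2). Sign convention follows the explicit-solvation bookkeeping:
#' `dA_es` and `dA_disp` are typically negative (stabilizing), `dA_cav`
#' positive, `e_reorg` small and positive.
#'
#' @param name character vector of unique solute names.
#' @param e_reorg,dA_es,dA_disp,dA_cav numeric, kcal/mol.
#' @param dA_hyd optional printed totals, kcal/mol.
#' @param exp_dA_hyd optional experimental values, kcal/mol.
#' @param asa optional surface areas, Angstrom^2.
#' @return data.frame of class `solute_table`.
#' @examples
#' solute_table("pyrene", e_reorg = 0.82, dA_es = -3.02,
#'              dA_disp = -19.70, dA_cav = 17.23)
#' @export
solute_table <- function(name, e_reorg, dA_es, dA_disp, dA_cav,
                         dA_hyd = NA_real_, exp_dA_hyd = NA_real_,
                         asa = NA_real_) {
  name <- as.character(name)
  n <- length(name)
  if (n == 0L) {
    tab <- data.frame(name = character(), dA_hyd = numeric(),
                      e_reorg = numeric(), dA_es = numeric(),
                      dA_disp = numeric(), dA_cav = numeric(),
                      exp_dA_hyd = numeric(), asa = numeric())
    class(tab) <- c("solute_table", "data.frame")
    return(tab)
  }
  if (any(!nzchar(name))) stop("solute names must be non-empty", call. = FALSE)
  if (anyDuplicated(name)) {
    stop("duplicate solute name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  }
  num <- function(v, what, required) {
    v <- rep_len(as.numeric(v), n)
    if (required && any(!is.finite(v))) {
      stop("component '", what, "' has missing/non-finite values",
           call. = FALSE)
    }
    v
  }
  tab <- data.frame(
    name = name,
    dA_hyd = rep_len(as.numeric(dA_hyd), n),
    e_reorg = num(e_reorg, "e_reorg", TRUE),
    dA_es = num(dA_es, "dA_es", TRUE),
    dA_disp = num(dA_disp, "dA_disp", TRUE),
    dA_cav = num(dA_cav, "dA_cav", TRUE),
    exp_dA_hyd = rep_len(as.numeric(exp_dA_hyd), n),
    asa = rep_len(as.numeric(asa), n),
    stringsAsFactors = FALSE)
  class(tab) <- c("solute_table", "data.frame")
  tab
}

#' Compose hydration free-energy sums from components
#'
#' Pure arithmetic on the stored components:
#' `dA_wat = dA_es + dA_disp + dA_cav`, `dA_non_es = dA_disp + dA_cav`, and
#' `dA_hyd = e_reorg + dA_wat`. No rounding is applied; when the input
#' components were independently rounded (as in published tables), the
#' recomposed total can differ from a printed total by up to about twice the
#' rounding unit.
#'
#' @param tab a [solute_table()] (or any data.frame with the component
#'   columns).
#' @return data.frame with columns `name`, `dA_wat`, `dA_non_es`, `dA_hyd`.
#' @examples
#' tab <- solute_table("pyrene", 0.82, -3.02, -19.70, 17.23)
#' compose(tab)$dA_hyd   # -4.67
#' @export
compose <- function(tab) {
  need <- c("e_reorg", "dA_es", "dA_disp", "dA_cav")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("missing component column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (f in need) {
    if (any(!is.finite(tab[[f]]))) {
      stop("component '", f, "' has missing/non-finite values", call. = FALSE)
    }
  }
  dA_wat <- tab$dA_es + tab$dA_disp + tab$dA_cav
  data.frame(name = if ("name" %in% names(tab)) tab$name else
               as.character(seq_len(nrow(tab))),
             dA_wat = dA_wat,
             dA_non_es = tab$dA_disp + tab$dA_cav,
             dA_hyd = tab$e_reorg + dA_wat,
             stringsAsFactors = FALSE)
}

#' Read a solute component table from delimited text
#'
#' Comma-separated, "." decimal, UTF-8; required header columns
#' `name,dA_hyd,e_reorg,dA_es,dA_disp,dA_cav` with optional `exp_dA_hyd` and
#' `asa`. Unicode minus signs are normalized to ASCII before numeric parsing,
#' so tables copied from typeset sources load unchanged.
#'
#' @param path file path.
#' @return A [solute_table()]. An empty data section yields an empty table
#'   with a warning.
#' @examples
#' path <- system.file("extdata", "aromatic_components.csv",
#'                     package = "hydrodecomp")
#' tab <- load_component_table(path)
#' tab$name
#' @export
load_component_table <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE, encoding = "UTF-8")
  txt <- gsub("−", "-", txt)   # Unicode minus -> ASCII hyphen-minus
  raw <- read.csv(text = paste(txt, collapse = "\n"), header = TRUE,
                  stringsAsFactors = FALSE, strip.white = TRUE,
                  colClasses = "character")
  miss <- setdiff(.component_cols, names(raw))
  if (length(miss) > 0L) {
    stop("component table header lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("component table has no data rows: ", path)
    return(solute_table(character(), numeric(), numeric(), numeric(),
                        numeric()))
  }
  parse_num <- function(col, required) {
    v <- raw[[col]]
    if (is.null(v)) return(rep(NA_real_, nrow(raw)))
    blank <- is.na(v) | !nzchar(trimws(v))
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!blank & is.na(out))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                   v[bad[1L]], col, bad[1L]), call. = FALSE)
    }
    if (required && any(blank)) {
      stop(sprintf("missing value in required column '%s' at data row %d",
                   col, which(blank)[1L]), call. = FALSE)
    }
    out
  }
  solute_table(
    name = raw$name,
    dA_hyd = parse_num("dA_hyd", FALSE),
    e_reorg = parse_num("e_reorg", TRUE),
    dA_es = parse_num("dA_es", TRUE),
    dA_disp = parse_num("dA_disp", TRUE),
    dA_cav = parse_num("dA_cav", TRUE),
    exp_dA_hyd = parse_num("exp_dA_hyd", FALSE),
    asa = parse_num("asa", FALSE))
}

#' Write a solute component table as delimited text
#'
#' Inverse of [load_component_table()]; numbers are written with full
#' precision (round-trips to the stored values).
#'
#' @param tab a [solute_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(tab, path) {
  cols <- c(.component_cols, .optional_cols)
  out <- as.data.frame(tab)[, intersect(cols, names(tab)), drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Check internal consistency of a component table
#'
#' Recomposes each solute's total via [compose()] and compares it with the
#' printed `dA_hyd`. Deviations above `tol` are flagged. The default
#' tolerance 0.015 kcal/mol allows for components independently rounded to
#' 0.01 kcal/mol.
#'
#' @param tab a [solute_table()] with `dA_hyd` present (rows with a missing
#'   printed total are skipped with a warning).
#' @param tol flag threshold, kcal/mol.
#' @return data.frame of class `consistency_report` with columns `name`,
#'   `dA_hyd_printed`, `dA_hyd_computed`, `deviation`, `flagged`.
#' @examples
#' tab <- load_component_table(system.file("extdata",
#'   "aromatic_components.csv", package = "hydrodecomp"))
#' check_consistency(tab)
#' @export
check_consistency <- function(tab, tol = 0.015) {
  stopifnot(is.numeric(tol), tol >= 0)
  has_printed <- is.finite(tab$dA_hyd)
  if (!all(has_printed)) {
    warning("skipping ", sum(!has_printed),
            " record(s) without a printed dA_hyd")
  }
  tab2 <- tab[has_printed, , drop = FALSE]
  comp <- compose(tab2)
  dev <- abs(comp$dA_hyd - tab2$dA_hyd)
  rep <- data.frame(name = tab2$name,
                    dA_hyd_printed = tab2$dA_hyd,
                    dA_hyd_computed = comp$dA_hyd,
                    deviation = dev,
                    flagged = dev > tol,
                    stringsAsFactors = FALSE)
  attr(rep, "tol") <- tol
  class(rep) <- c("consistency_report", "data.frame")
  rep
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> %d record(s), tol %.3g kcal/mol: %d flagged, max deviation %.4f\n",
              nrow(x), attr(x, "tol"), sum(x$flagged),
              if (nrow(x)) max(x$deviation) else 0))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Weeks-Chandler-Andersen split of a Lennard-Jones potential
#'
#' Splits u_LJ(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6) at its minimum
#' r_min = 2^(1/6) sigma into a purely repulsive branch
#' (u_LJ + eps for r < r_min, else 0) and a purely attractive branch
#' (-eps for r < r_min, else u_LJ). The two branches sum to u_LJ for every r.
#' This is the split used to separate the cavitation (repulsive-core) and
#' dispersion (attractive) contributions in explicit-solvation free-energy
#' decompositions.
#'
#' @param r separation(s), Angstrom; must be > 0.
#' @param epsilon LJ well depth, kcal/mol (> 0).
#' @param sigma LJ size parameter, Angstrom (> 0).
#' @return data.frame with columns `r`, `u_lj`, `u_repulsive`, `u_attractive`
#'   (kcal/mol).
#' @examples
#' wca_split(2^(1/6) * 3.4, epsilon = 0.25, sigma = 3.4)
#' @export
wca_split <- function(r, epsilon, sigma) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("separation r must be positive and finite", call. = FALSE)
  }
  sr6 <- (sigma / r)^6
  u_lj <- 4 * epsilon * (sr6^2 - sr6)
  r_min <- 2^(1 / 6) * sigma
  inside <- r < r_min
  u_rep <- ifelse(inside, u_lj + epsilon, 0)
  u_att <- ifelse(inside, -epsilon, u_lj)
  data.frame(r = r, u_lj = u_lj, u_repulsive = u_rep, u_attractive = u_att)
}
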