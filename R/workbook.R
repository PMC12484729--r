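#' Workbook layout: id assignment and label dictionary
#'
#' Builds the id/label machinery of the published-data layout: numeric ids
#' are assigned densely, in label-dictionary order, to indicators,
#' categories, states and areas. Every id that appears in a data sheet must
#' resolve in the label dictionary.
#'
#' @param indicators data.frame `indicator_id, label, category`.
#' @param states data.frame `state_id, label`.
#' @param areas data.frame `area_id, state_id, label`.
#' @param level `"district"` or `"pc"`, controls the fifth sheet's name.
#' @return object of class `workbook_layout` with the `dictionary`
#'   data.frame (`entity, id, code, label`) and numeric id lookup tables.
#' @export
workbook_layout <- function(indicators, states, areas,
                            level = c("district", "pc")) {
  level <- match.arg(level)
  if (!nrow(indicators)) stop("empty indicator list")
  categories <- unique(indicators$category)
  dict <- rbind(
    data.frame(entity = "category", id = seq_along(categories),
               code = categories, label = categories,
               stringsAsFactors = FALSE),
    data.frame(entity = "indicator", id = seq_len(nrow(indicators)),
               code = indicators$indicator_id, label = indicators$label,
               stringsAsFactors = FALSE),
    data.frame(entity = "state", id = seq_len(nrow(states)),
               code = states$state_id, label = states$label,
               stringsAsFactors = FALSE),
    data.frame(entity = "area", id = seq_len(nrow(areas)),
               code = areas$area_id, label = areas$label,
               stringsAsFactors = FALSE)
  )
  structure(list(dictionary = dict, level = level,
                 area_state = stats::setNames(areas$state_id, areas$area_id)),
            class = "workbook_layout")
}

.wb_id <- function(layout, entity, code) {
  d <- layout$dictionary
  idx <- match(code, d$code[d$entity == entity])
  if (anyNA(idx)) {
    stop("unlabeled ", entity, " id(s): ",
         paste(unique(code[is.na(idx)]), collapse = ", "))
  }
  d$id[d$entity == entity][idx]
}

.wb_python <- function() {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("workbook export needs a python interpreter with ",
                     "openpyxl on the PATH")
  py
}

#' Export the five-sheet results workbook
#'
#' Writes the layered results file: (1) sheet and column description,
#' (2) label dictionary, (3) national estimates, (4) indicator-state data,
#' (5) indicator-area data (district or constituency). Prevalences are
#' printed to one decimal. A CSV mirror of every sheet is always written
#' next to the workbook (`<path>_<n>_<sheet>.csv`) — the mirrors are the
#' diff- and determinism-friendly artifact; the XLSX itself is produced by
#' the bundled openpyxl bridge.
#'
#' @param national data.frame `indicator_id, round, prevalence` (plus
#'   optional `headcount`, `change_pp`).
#' @param state_est data.frame `indicator_id, state_id, round, prevalence`.
#' @param area_est data.frame `indicator_id, area_id, round, prevalence,
#'   lo95, hi95` plus optional `headcount, rank, decile, change_pp,
#'   change_category`.
#' @param layout a [workbook_layout()].
#' @param path output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
export_workbook <- function(national, state_est, area_est, layout, path) {
  stopifnot(inherits(layout, "workbook_layout"))
  if (!nrow(national)) stop("empty indicator list: nothing to export")

  fmt1 <- function(x) ifelse(is.na(x), NA, sprintf("%.1f", x))
  desc <- data.frame(
    sheet = c("Sheet & Column Description", "Label Dictionary",
              "National Estimates", "Indicator-State Data",
              paste0("Indicator-", if (layout$level == "district")
                "District" else "PC", " Data")),
    description = c(
      "This sheet: what each sheet and column contains.",
      "Numeric id to label mapping for categories, indicators, states and areas.",
      "All-India prevalence, headcount and change by indicator and round.",
      "State-level prevalence by indicator and round.",
      "Area-level prevalence with 95% credible interval, headcount, rank, decile and change category."),
    stringsAsFactors = FALSE)

  nat <- data.frame(indicator_id = .wb_id(layout, "indicator",
                                          national$indicator_id),
                    round = national$round,
                    prevalence = fmt1(national$prevalence),
                    stringsAsFactors = FALSE)
  for (col in c("headcount", "change_pp")) {
    if (col %in% names(national)) nat[[col]] <- national[[col]]
  }

  st <- data.frame(indicator_id = .wb_id(layout, "indicator",
                                         state_est$indicator_id),
                   state_id = .wb_id(layout, "state", state_est$state_id),
                   round = state_est$round,
                   prevalence = fmt1(state_est$prevalence),
                   stringsAsFactors = FALSE)

  ar <- data.frame(indicator_id = .wb_id(layout, "indicator",
                                         area_est$indicator_id),
                   area_id = .wb_id(layout, "area", area_est$area_id),
                   state_id = .wb_id(layout, "state",
                                     unname(layout$area_state[area_est$area_id])),
                   round = area_est$round,
                   prevalence = fmt1(area_est$prevalence),
                   lo95 = fmt1(area_est$lo95),
                   hi95 = fmt1(area_est$hi95),
                   stringsAsFactors = FALSE)
  for (col in c("headcount", "rank", "decile", "change_pp",
                "change_category")) {
    if (col %in% names(area_est)) {
      ar[[col]] <- if (col == "change_pp") fmt1(area_est[[col]])
                   else area_est[[col]]
    }
  }

  sheets <- list(desc, layout$dictionary, nat, st, ar)
  names(sheets) <- desc$sheet

  mirrors <- character(length(sheets))
  base <- sub("\\.xlsx$", "", path)
  for (i in seq_along(sheets)) {
    safe <- gsub("[^A-Za-z0-9_-]+", "_", names(sheets)[i])
    mirrors[i] <- paste0(base, "_", i, "_", safe, ".csv")
    utils::write.csv(sheets[[i]], mirrors[i], row.names = FALSE, na = "")
  }

  script <- system.file("python", "workbook.py", package = "prevsae")
  args <- c(script, "write", path, rbind(names(sheets), mirrors))
  status <- system2(.wb_python(), shQuote(args))
  if (status != 0) stop("workbook export failed (openpyxl bridge exit ",
                        status, ")")
  invisible(path)
}

#' Read a results workbook back
#'
#' Round-trips the workbook through the openpyxl bridge: every sheet is
#' dumped to CSV and read back as a data.frame.
#'
#' @param path an `.xlsx` written by [export_workbook()].
#' @return named list of data.frames, one per sheet, in sheet order.
#' @export
read_workbook <- function(path) {
  tmp <- tempfile("wb_read_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  script <- system.file("python", "workbook.py", package = "prevsae")
  out <- system2(.wb_python(), shQuote(c(script, "read", path, tmp)),
                 stdout = TRUE)
  status <- attr(out, "status") %||% 0L
  if (status != 0) stop("workbook read failed (openpyxl bridge exit ",
                        status, ")")
  files <- sort(list.files(tmp, pattern = "\\.csv$", full.names = TRUE))
  sheets <- lapply(files, utils::read.csv, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(sheets) <- out
  sheets
}
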