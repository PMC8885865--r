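#' Load and validate an entity catalog
#'
#' The catalog maps opaque knowledge-base entity identifiers (e.g.
#' `"/m/09728"` for bread) to the study taxonomy: food entities carry one of
#' the food-category names; food-access-mode entities carry the orthogonal
#' 2x2 classification of where food is consumed (`home` / `outside`) and who
#' prepares it (`household` / `third_party`).
#'
#' Required CSV columns: `entity_id`, `display_name`, `kind`, `category`,
#' `access_home`, `access_preparer` (UTF-8, header row). `kind` is `food` or
#' `access_mode`; food entries must have a non-empty `category`; access-mode
#' entries must have both access fields.
#'
#' @param path CSV file path.
#' @return an object of class `entity_catalog`: list with `entries` (tibble).
#' @export
load_catalog <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  need <- c(
    "entity_id", "display_name", "kind", "category",
    "access_home", "access_preparer"
  )
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("load_catalog: missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  blank <- function(x) is.na(x) | x == ""
  if (anyDuplicated(df$entity_id)) {
    stop("load_catalog: duplicate entity_id(s): ",
      paste(unique(df$entity_id[duplicated(df$entity_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(df$kind %in% c("food", "access_mode"))) {
    stop("load_catalog: kind must be 'food' or 'access_mode'", call. = FALSE)
  }
  food <- df$kind == "food"
  if (any(food & blank(df$category))) {
    stop("load_catalog: food entities without a category: ",
      paste(df$entity_id[food & blank(df$category)], collapse = ", "),
      call. = FALSE
    )
  }
  am <- df$kind == "access_mode"
  if (any(am & (blank(df$access_home) | blank(df$access_preparer)))) {
    stop("load_catalog: access_mode entities must have both access_home ",
      "and access_preparer",
      call. = FALSE
    )
  }
  if (!all(df$access_home[am] %in% c("home", "outside"))) {
    stop("load_catalog: access_home must be 'home' or 'outside'",
      call. = FALSE
    )
  }
  if (!all(df$access_preparer[am] %in% c("household", "third_party"))) {
    stop("load_catalog: access_preparer must be 'household' or 'third_party'",
      call. = FALSE
    )
  }
  message(
    "load_catalog: ", sum(food), " food entities in ",
    length(unique(df$category[food])), " categories; ",
    sum(am), " access-mode entities"
  )
  structure(list(entries = tibble::as_tibble(df)), class = "entity_catalog")
}

#' @export
print.entity_catalog <- function(x, ...) {
  e <- x$entries
  cat(
    "<entity_catalog> ", sum(e$kind == "food"), " food entities (",
    length(unique(e$category[e$kind == "food"])), " categories), ",
    sum(e$kind == "access_mode"), " access-mode entities\n",
    sep = ""
  )
  invisible(x)
}

#' Entity membership of taxonomy groups
#'
#' `food_category_members()` returns, per food category, the entity ids in it.
#' `access_mode_members()` returns the four cells of the 2x2 access-mode
#' grouping, keyed `<access_home>_<access_preparer>` (e.g.
#' `home_household` for food prepared within the household and consumed at
#' home).
#'
#' @param catalog an `entity_catalog`.
#' @return named list of character vectors of entity ids.
#' @export
food_category_members <- function(catalog) {
  e <- catalog$entries[catalog$entries$kind == "food", ]
  split(e$entity_id, e$category)
}

#' @rdname food_category_members
#' @export
access_mode_members <- function(catalog) {
  e <- catalog$entries[catalog$entries$kind == "access_mode", ]
  split(e$entity_id, paste(e$access_home, e$access_preparer, sep = "_"))
}

#' Aggregate per-entity series into a group series
#'
#' Calibrated volumes share one multiplicative scale, so the combined
#' interest in a set of entities is the week-wise sum of the member series.
#'
#' @param per_entity list of [interest_series()], labelled by entity id.
#' @param members character vector of entity ids to aggregate (non-empty).
#' @param label label for the aggregated series.
#' @return an [interest_series()] with the week-wise summed volumes.
#' @export
aggregate_series <- function(per_entity, members, label = "group") {
  if (length(members) == 0L) {
    stop("aggregate_series: empty member list", call. = FALSE)
  }
  labels <- vapply(per_entity, function(s) s$label, character(1))
  idx <- match(members, labels)
  if (anyNA(idx)) {
    stop("aggregate_series: member series not found: ",
      paste(members[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  sel <- per_entity[idx]
  first <- sel[[1]]
  for (s in sel[-1]) {
    if (!identical(s$country, first$country)) {
      stop("aggregate_series: member series span different countries",
        call. = FALSE
      )
    }
    if (!same_week_grid(s, first)) {
      stop("aggregate_series: member series have mismatched week grids",
        call. = FALSE
      )
    }
  }
  total <- Reduce(`+`, lapply(sel, function(s) s$data$volume))
  interest_series(
    country = first$country, label = label,
    year = first$data$year, week = first$data$week, volume = total
  )
}
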