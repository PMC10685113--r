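#' Bill of materials for the heater electronics
#'
#' Reads the packaged bill of materials (electronics and heating
#' components). Prices are carried as exact integer cents to avoid
#' binary-float drift in sums.
#'
#' @param path Path to a BOM YAML file; default the packaged list.
#' @return A data frame of class `bom_table` with columns `name`, `price`
#'   (numeric EUR) and `cents` (integer).
#' @export
bom_table <- function(path = system.file("extdata", "bom_electronics.yaml",
                                         package = "thermocyte")) {
  raw <- yaml::read_yaml(path)
  items <- raw$items
  if (!length(items)) {
    out <- data.frame(name = character(0), price = numeric(0),
                      cents = integer(0))
  } else {
    cents <- vapply(items, function(it) {
      p <- as.character(it$price)
      if (!grepl("^[0-9]+(\\.[0-9]{1,2})?$", p))
        stop("bom_table: malformed (or negative) price: ", p)
      as.integer(round(as.numeric(p) * 100))
    }, integer(1))
    out <- data.frame(name = vapply(items, `[[`, character(1), "name"),
                      price = cents / 100, cents = cents,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("bom_table", "data.frame")
  out
}

#' Total cost of a bill of materials
#'
#' Exact decimal sum of item prices (integer-cent arithmetic).
#'
#' @param items A `bom_table` data frame (or any data frame with a `cents`
#'   integer column).
#' @return Total in currency units (numeric, exact to the cent).
#' @examples
#' \dontrun{bom_total(bom_table())  # 201.00}
#' @export
bom_total <- function(items = bom_table()) {
  if (nrow(items) == 0) return(0)
  sum(as.numeric(items$cents)) / 100
}
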