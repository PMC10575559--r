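#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

#' The two items of the game
#'
#' Every stage of the game involves exactly two items; by the sum constraints
#' all scalars are stored in apple coordinates.
#'
#' @format Character vector `c("apple", "orange")`.
#' @export
ITEMS <- c("apple", "orange")

#' The other item
#'
#' @param item `"apple"` or `"orange"` (vectorised).
#' @return The opposite label.
#' @examples
#' other_item("apple")
#' @export
other_item <- function(item) {
  item <- check_item(item)
  ifelse(item == "apple", "orange", "apple")
}

check_item <- function(item) {
  item <- as.character(item)
  if (!all(item %in% ITEMS))
    rlang::abort("items must be \"apple\" or \"orange\"",
                 class = "tommarket_item_error")
  item
}

#' One maze instantiation
#'
#' A scenario fixes the distance to the apple and the buyer's reward from
#' consuming it. The orange values are derived from the sum constraint and
#' never stored, so the constraint cannot be violated.
#'
#' @param d_apple Distance to the apple, in `[0, sum_total]`.
#' @param r_apple Reward of the apple, in `[0, sum_total]`.
#' @param config A [tom_config()].
#' @return An object of class `tom_scenario` with derived accessors for the
#'   orange side.
#' @examples
#' sc <- tom_scenario(d_apple = 2, r_apple = 8, tom_config())
#' stage1_utility(sc, "apple")
#' @export
tom_scenario <- function(d_apple, r_apple, config = tom_config()) {
  stopifnot(inherits(config, "tom_config"))
  S <- config$sum_total
  if (!is.numeric(d_apple) || length(d_apple) != 1 || d_apple < 0 || d_apple > S)
    config_error("d_apple", sprintf("must lie in [0, %g]", S))
  if (!is.numeric(r_apple) || length(r_apple) != 1 || r_apple < 0 || r_apple > S)
    config_error("r_apple", sprintf("must lie in [0, %g]", S))
  structure(list(d_apple = as.numeric(d_apple), r_apple = as.numeric(r_apple),
                 sum_total = S),
            class = "tom_scenario")
}

scenario_r <- function(scenario, item) {
  ifelse(item == "apple", scenario$r_apple, scenario$sum_total - scenario$r_apple)
}

scenario_d <- function(scenario, item) {
  ifelse(item == "apple", scenario$d_apple, scenario$sum_total - scenario$d_apple)
}

#' A seller price schedule
#'
#' Prices sum to `sum_total`, so a schedule is its apple price; the orange
#' price is derived.
#'
#' @param m_apple Price of the apple, in `[0, sum_total]`.
#' @param config A [tom_config()].
#' @return An object of class `tom_price_schedule`.
#' @export
price_schedule <- function(m_apple, config = tom_config()) {
  stopifnot(inherits(config, "tom_config"))
  S <- config$sum_total
  if (!is.numeric(m_apple) || length(m_apple) != 1 || m_apple < 0 || m_apple > S)
    config_error("m_apple", sprintf("must lie in [0, %g]", S))
  structure(list(m_apple = as.numeric(m_apple), sum_total = S),
            class = "tom_price_schedule")
}

schedule_m <- function(prices, item) {
  ifelse(item == "apple", prices$m_apple, prices$sum_total - prices$m_apple)
}

#' First-stage utility of the buyer
#'
#' The immediate utility of walking to and consuming an item: the reward of
#' the item minus the cost incurred through the distance travelled (unit cost
#' per step).
#'
#' @param scenario A [tom_scenario()].
#' @param choice `"apple"` or `"orange"`.
#' @return Scalar utility in reward units.
#' @export
stage1_utility <- function(scenario, choice) {
  stopifnot(inherits(scenario, "tom_scenario"))
  choice <- check_item(choice)
  scenario_r(scenario, choice) - scenario_d(scenario, choice)
}

#' Third-stage utility of the buyer
#'
#' The utility of purchasing and consuming an item at the seller's posted
#' price: reward minus price. No travel cost applies at this stage.
#'
#' @param scenario A [tom_scenario()].
#' @param prices A [price_schedule()].
#' @param choice `"apple"` or `"orange"`.
#' @return Scalar utility in reward units.
#' @export
stage3_utility <- function(scenario, prices, choice) {
  stopifnot(inherits(scenario, "tom_scenario"),
            inherits(prices, "tom_price_schedule"))
  choice <- check_item(choice)
  scenario_r(scenario, choice) - schedule_m(prices, choice)
}

#' Seller reward
#'
#' The seller is paid exactly the posted price of whichever item the buyer
#' buys.
#'
#' @param prices A [price_schedule()].
#' @param bought The item purchased at stage 3.
#' @return Scalar revenue in money units.
#' @export
seller_reward <- function(prices, bought) {
  stopifnot(inherits(prices, "tom_price_schedule"))
  schedule_m(prices, check_item(bought))
}

#' Total (undiscounted) buyer utility over the game
#'
#' @param scenario A [tom_scenario()].
#' @param prices A [price_schedule()].
#' @param first Item consumed at stage 1.
#' @param third Item purchased at stage 3.
#' @return Sum of the stage-1 and stage-3 utilities.
#' @export
total_buyer_utility <- function(scenario, prices, first, third) {
  stage1_utility(scenario, first) + stage3_utility(scenario, prices, third)
}
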