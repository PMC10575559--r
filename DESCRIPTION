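Package: tommarket
Title: Recursive Theory-of-Mind Buyer-Seller Game and Deception Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a three-stage buyer-seller signalling game in which
    both agents carry a recursive theory of mind. A buyer first walks to one of
    two items (revealing information through its choice), a seller performs
    Bayesian inverse reinforcement learning on that observation and prices the
    items, and the buyer then purchases one item. Agents are tabulated level by
    level along a strict cognitive hierarchy: a naive reward-maximising buyer,
    an inverting seller, a buyer that plans through the seller's inference, a
    skeptical seller, and a cornered third-order buyer. Information-theoretic
    instruments (mutual information between preferences and actions, prior-to-
    posterior Kullback-Leibler divergence, assumed-versus-actual policy
    divergence) quantify the deception and skepticism that emerge from pure
    reward maximisation. Includes deterministic sweep experiments, CSV/JSON
    export, figure rendering and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    optparse,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
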