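Package: ventelast
Title: Model-Based Lung Elastance Identification and PEEP Titration Support
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies patient-specific respiratory mechanics from ventilator
    airway pressure and flow waveforms using a single-compartment linear lung
    model. Constant lung elastance and resistance are estimated per breath by an
    integral-based least-squares method; time-variant (dynamic) elastance is
    estimated over short windows within each inspiration. Derived metrics include
    the dynamic-elastance area (the time integral of dynamic elastance over
    inspiration, proportional to elastic work of breathing) and the
    elastic/resistive decomposition of work of breathing. PEEP selection rules
    (minimum elastance, minimum dynamic-elastance area, and the inflection
    method on the descending limb of the elastance-PEEP curve) are applied
    across a recruitment-manoeuvre titration. A forward simulator of
    volume-controlled ventilation with known ground truth supports validation,
    and a command-line interface ties the identify-summarize-select pipeline
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
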