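Package: phonalign
Title: Text-Independent Forced Alignment for Clinical Speech Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Text-independent forced alignment of phone-level speech
    annotations from two model-agnostic inputs: a timed phoneme-token
    stream (a CTC recognizer's per-frame output) and an unlabelled
    segment boundary list (an unsupervised segmenter's output). Builds
    biased nearest-neighbour class regions over the utterance timeline,
    labels each segment by maximum temporal overlap, amalgamates
    overfitted duplicate segments with transition-aware soft or hard
    cleaning, optionally removes boundaries in non-speech via a
    frame-energy voice activity detector, and scores alignments against
    TIMIT-style PHN ground truth with midpoint and onset evaluation
    protocols. Includes a synthetic corpus generator emulating
    recognizer and segmenter error modes so the full pipeline is
    testable without audio corpora, plus PHN, Praat TextGrid and WAV
    (PCM16 mono) input/output.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
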