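#include <Rcpp.h>
using namespace Rcpp;

// Per-reading counter state machine.
//
// Inputs are per-reading vectors over the samples that fall inside the
// recording window:
//   posture:   1 if the normalized z-axis value exceeds the sitting
//              threshold (sitting rule), 2 otherwise (standing rule)
//   step_trig: true when the dynamic acceleration magnitude exceeds the
//              step trigger, i.e. "the sensor detects an acceleration"
//   monitored: true when the reading lies inside a connected interval
//
// Labels: 0 = unmonitored, 1 = sitting, 2 = standing, 3 = stepping.
//
// Semantics: while the step counter runs, readings are provisionally
// labelled stepping and each quiet reading increments exactly one posture
// counter (the other is zeroed; a triggered reading zeroes both). When a
// posture counter reaches counter_limit the last counter_limit readings are
// committed retroactively to that posture, the step counter stops, and
// subsequent quiet readings carry the committed posture until the next
// trigger. State resets across unmonitored gaps: a commit never reaches
// back across a disconnection.
// [[Rcpp::export]]
IntegerVector run_state_machine(IntegerVector posture,
                                LogicalVector step_trig,
                                LogicalVector monitored,
                                int counter_limit) {
  const int n = posture.size();
  if (step_trig.size() != n || monitored.size() != n)
    stop("posture, step_trig and monitored must have equal length");
  if (counter_limit < 1) stop("counter_limit must be >= 1");

  IntegerVector label(n);
  int mode = 3, sit_c = 0, stand_c = 0;

  for (int i = 0; i < n; ++i) {
    if (!monitored[i]) {
      label[i] = 0;
      mode = 3; sit_c = 0; stand_c = 0;
      continue;
    }
    if (step_trig[i]) {
      sit_c = 0; stand_c = 0; mode = 3;
      label[i] = 3;
      continue;
    }
    if (posture[i] == 1) { ++sit_c; stand_c = 0; }
    else                 { ++stand_c; sit_c = 0; }
    label[i] = mode;
    if (sit_c >= counter_limit) {
      for (int j = i - counter_limit + 1; j <= i; ++j) label[j] = 1;
      mode = 1; sit_c = 0; stand_c = 0;
    } else if (stand_c >= counter_limit) {
      for (int j = i - counter_limit + 1; j <= i; ++j) label[j] = 2;
      mode = 2; sit_c = 0; stand_c = 0;
    }
  }
  return label;
}
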