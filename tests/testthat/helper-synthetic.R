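# Shared fixtures, built in code at test time.

# compact protocol: M3 15-20, A1 31-36, V1 47-52, K 63-68 (fits T = 70-80)
test_protocol <- function() default_protocol()

# n somata on a grid inside a ny x nx field
test_positions <- function(n, ny = 64, nx = 64, radius = 4)
  calciscope:::grid_positions(n, ny, nx, radius)

# truth with every cell expressing the given channels
uniform_truth <- function(n = 8, channels = c("M3", "V1"), ...,
                          ny = 64, nx = 64, radius = 4) {
  calcium_truth(test_positions(n, ny, nx, radius), radius,
                expressed = replicate(n, channels, simplify = FALSE), ...)
}

# noisy trace with an optional step transient inside the stimulus window
step_trace <- function(T, stim_start, amp_sd, noise_sd = 1, tau = 8) {
  sig <- numeric(T)
  t <- stim_start:T
  sig[t] <- amp_sd * noise_sd * exp(-(t - stim_start) / tau)
  sig + stats::rnorm(T, 0, noise_sd)
}

# best ground-truth Jaccard for each true region against a label image
branch_jaccards <- function(label, truth_label) {
  vapply(seq_len(max(truth_label)), function(b) {
    tm <- truth_label == b
    if (max(label) == 0L) return(0)
    max(vapply(seq_len(max(label)), function(k)
      calciscope:::jaccard(label == k, tm), numeric(1)))
  }, numeric(1))
}

# protocol window helpers (internal access kept in one place)
stim_window_frames_ <- function(p, i) calciscope:::stim_window_frames(p, i)
pre_window_frames_ <- function(p, i) calciscope:::pre_window_frames(p, i)
n_rois_ <- function(r) nrow(r$table)
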