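# Hand-built record/bedtime constructors used across the suite.

mk_records <- function(child_id, day_index, day_type, clock_time,
                       energy_kcal, time_status = "ok", label = NA_character_) {
  n <- max(length(child_id), length(day_index), length(day_type),
           length(clock_time), length(energy_kcal))
  data.table::data.table(
    child_id = rep_len(as.character(child_id), n),
    day_index = rep_len(as.integer(day_index), n),
    day_type = rep_len(as.character(day_type), n),
    clock_time = rep_len(as.integer(clock_time), n),
    time_status = rep_len(time_status, n),
    energy_kcal = rep_len(as.numeric(energy_kcal), n),
    label = rep_len(as.character(label), n))
}

mk_bedtimes <- function(child_id, weekday, weekend) {
  data.table::data.table(
    child_id = as.character(child_id),
    weekday_bedtime = as.integer(weekday),
    weekend_bedtime = as.integer(weekend),
    source = "individual")
}

# one child, 2 weekday + 1 weekend days, regular meals + evening snack
tiny_child <- function(id = "k1") {
  rbind(
    mk_records(id, 1, "weekday", c(480, 780, 1065, 1200),
               c(350, 450, 500, 120)),
    mk_records(id, 2, "weekday", c(470, 790, 1080, 1215),
               c(300, 420, 480, 100)),
    mk_records(id, 3, "weekend", c(500, 770, 1100), c(320, 400, 520)))
}
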