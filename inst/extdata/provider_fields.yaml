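# Provider export dialects: external field name -> canonical name.
# Covers id/date keys, the provider's analysis variables and the inputs
# of its valid-day rule. Unmapped or out-of-capability columns in an
# export are dropped with a warning at load time.
fitbit:
  user_id: participant_id
  dateTime: date
  steps: steps
  caloriesOut: tee
  activityCalories: aee
  minutesLightlyActive: lpa
  minutesFairlyActive: mpa
  minutesVeryActive: vpa
  minutesAsleep: sleep
garmin:
  userId: participant_id
  calendarDate: date
  totalSteps: steps
  totalKilocalories: tee
  activeKilocalories: aee
  moderateIntensityMinutes: mpa
  vigorousIntensityMinutes: vpa
  sleepMinutes: sleep
  sedentaryMinutes: sedentary
  lightIntensityMinutes: lpa
apple:
  userId: participant_id
  day: date
  stepCount: steps
  activeEnergyBurned: aee
  basalEnergyBurned: ree
  sleepMinutes: sleep
googlefit:
  user_id: participant_id
  date: date
  step_count: steps
  calories_expended: tee
oura:
  user_id: participant_id
  summary_date: date
  steps: steps
  cal_total: tee
  cal_active: aee
  inactive_minutes: sedentary
  low_minutes: lpa
  medium_minutes: mpa
  high_minutes: vpa
  non_wear_minutes: nonwear
polar:
  member_id: participant_id
  date: date
  active_steps: steps
  calories: tee
  active_calories: aee
  sedentary_minutes: sedentary
  light_minutes: lpa
  moderate_minutes: mpa
  vigorous_minutes: vpa
  sleep_minutes: sleep
  non_wear_minutes: nonwear
samsung:
  uid: participant_id
  day_time: date
  step_count: steps
  active_calorie: aee
  sleep_minutes: sleep
  sedentary_minutes: sedentary
  light_minutes: lpa
  moderate_minutes: mpa
  vigorous_minutes: vpa
withings:
  userid: participant_id
  date: date
  steps: steps
  totalcalories: tee
  calories: aee
  soft: lpa
  moderate: mpa
  intense: vpa
  sleep_minutes: sleep
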