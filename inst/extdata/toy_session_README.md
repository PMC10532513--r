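# Toy session: hand-computed oracle for the scorer

`toy_session.csv` is a synthetic, hand-built 20-trial session (2 blocks of
10 trials: 6 ANTI, 2 EV, 2 AV each) whose every core index is derived below
by hand. The test suite requires the scorer to reproduce these values
exactly (score with `minimal_blocks_completed = 0`, since the toy blocks
are deliberately short).

## Trials

Block 1 (ANTI rows: tone / cue / congruency / response / RT / fa-difficult):

| # | kind | tone | cue | congr | response | RT | correct | faDiff |
|---|------|------|-----|-------|----------|----|---------|--------|
| 0 | ANTI | no | none | con | left (ok) | 560 | T | F |
| 1 | ANTI | yes | none | con | right (ok) | 520 | T | F |
| 2 | ANTI | yes | valid | inc | left (ok) | 600 | T | F |
| 3 | ANTI | yes | invalid | inc | right (ok) | 660 | T | F |
| 4 | ANTI | yes | valid | con | wrong dir | 480 | F | T |
| 5 | ANTI | no | none | inc | spacebar (FA) | 450 | F | T |
| 6 | EV | yes | none | con | spacebar (hit) | 700 | T | — |
| 7 | EV | no | valid | inc | none (miss) | — | F | — |
| 8 | AV | — | — | — | any key | 420 | — | — |
| 9 | AV | — | — | — | any key | 650 | — | — |

Block 2:

| # | kind | tone | cue | congr | response | RT | correct | faDiff |
|---|------|------|-----|-------|----------|----|---------|--------|
| 10 | ANTI | no | none | con | left (ok) | 580 | T | F |
| 11 | ANTI | yes | none | con | right (ok) | 530 | T | F |
| 12 | ANTI | yes | valid | inc | left (ok) | 620 | T | T |
| 13 | ANTI | no | invalid | inc | right (ok) | 640 | T | F |
| 14 | ANTI | yes | invalid | con | left (ok) | 100 | T | T |
| 15 | ANTI | yes | valid | con | right (ok) | 1600 | T | F |
| 16 | EV | no | none | inc | spacebar (hit) | 800 | T | — |
| 17 | EV | yes | invalid | con | spacebar (hit) | 750 | T | — |
| 18 | AV | — | — | — | any key | 510 | — | — |
| 19 | AV | — | — | — | any key | 700 | — | — |

## RT-index trial pool

RT indexes use correct ANTI trials with RT in [200, 1500]. Excluded: #4
(error), #5 (FA/error), #14 (RT 100 < 200), #15 (RT 1600 > 1500). Pool:
560, 520, 600, 660, 580, 530, 620, 640.

## Hand computations

- overall RT = mean(pool) = 4710 / 8 = **588.75 ms**
- overall errors = 2 / 12 = **16.6667 %** (#4, #5)
- alerting RT (no-cue): no-tone mean (560, 580) = 570; tone mean (520, 530)
  = 525 -> **45 ms**
- alerting errors (no-cue, all trials): no-tone = {#0, #5, #10}: 1/3 =
  33.33 %; tone = {#1, #11}: 0 % -> **33.3333 %**
- orienting RT: invalid mean (660, 640) = 650; valid mean (600, 620) = 610
  -> **40 ms**
- orienting errors: invalid {#3, #13, #14}: 0 %; valid {#2, #4, #12, #15}:
  1/4 = 25 % -> **-25 %**
- congruency RT: incongruent mean (600, 660, 620, 640) = 630; congruent
  mean (560, 520, 580, 530) = 547.5 -> **82.5 ms**
- congruency errors: incongruent {#2, #3, #5, #12, #13}: 1/5 = 20 %;
  congruent {#0, #1, #4, #10, #11, #14, #15}: 1/7 = 14.2857 % ->
  **5.714286 %**
- hits = 3 / 4 = **75 %**; per block 1/2 = 50 % and 2/2 = 100 % -> slope
  over blocks (1, 2) = **+50 %/block**
- false alarms: fa-difficult trials {#4, #5, #12, #14}, spacebar on #5 only
  = 1 / 4 = **25 %**; per block 1/2 = 50 % and 0/2 = 0 % -> slope
  **-50 %/block**
- AV mean RT = mean(420, 650, 510, 700) = **570 ms**; per-block means 535
  and 605 -> slope **+70 ms/block**
- AV SD RT = sd(420, 650, 510, 700) = sqrt(49400 / 3) = **128.3225 ms**;
  per-block SDs 230/sqrt(2) = 162.6346 and 190/sqrt(2) = 134.3503 -> slope
  **-28.2843 ms/block**
- lapses (RT > 600 or none): {650, 700} = 2 / 4 = **50 %**; 50 % in each
  block -> slope **0**
- SDT (log-linear corrected): H = (3 + 0.5)/(4 + 1) = 0.7, FA =
  (1 + 0.5)/(4 + 1) = 0.3; d' = z(0.7) - z(0.3) = 2 x 0.5244005 =
  **1.0488010**; c = -(z(0.7) + z(0.3))/2 = **0**
- EV mean RT over hits = mean(700, 800, 750) = **750 ms**; EV SD RT =
  **50 ms**
- mean thought-probe rating: no TP rows -> **NA**
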