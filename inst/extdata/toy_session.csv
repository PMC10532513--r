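subject_id,session_number,session_date,participant_code,experiment,group,task_type,noise,difficulty,target_duration_ms,n_blocks,probes_per_block,trial_index,block,phase,kind,tone,cue,congruency,target_location,target_direction,target_displacement_px,jitter_px_1,jitter_px_2,jitter_px_3,jitter_px_4,jitter_px_5,fa_difficult,onset_ms,expected_response,response_class,rt_ms,correct,screen_full,probe_rating
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,0,1,experimental,ANTI,FALSE,none,congruent,up,left,0,0,0,0,0,0,FALSE,0,direction_key,direction_left,560,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,1,1,experimental,ANTI,TRUE,none,congruent,up,right,0,0,0,0,0,0,FALSE,4100,direction_key,direction_right,520,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,2,1,experimental,ANTI,TRUE,valid,incongruent,up,left,0,0,0,0,0,0,FALSE,8200,direction_key,direction_left,600,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,3,1,experimental,ANTI,TRUE,invalid,incongruent,up,right,0,0,0,0,0,0,FALSE,12300,direction_key,direction_right,660,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,4,1,experimental,ANTI,TRUE,valid,congruent,up,left,0,0,0,3,0,0,TRUE,16400,direction_key,direction_right,480,FALSE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,5,1,experimental,ANTI,FALSE,none,incongruent,up,right,0,0,0,3,0,0,TRUE,20500,direction_key,spacebar,450,FALSE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,6,1,experimental,EV,TRUE,none,congruent,down,left,8,0,0,0,0,0,,24600,spacebar,spacebar,700,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,7,1,experimental,EV,FALSE,valid,incongruent,down,left,-8,0,0,0,0,0,,28700,spacebar,none,,FALSE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,8,1,experimental,AV,,,,,,,,,,,,,32800,any_key,any_key,420,,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,9,1,experimental,AV,,,,,,,,,,,,,36900,any_key,any_key,650,,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,10,2,experimental,ANTI,FALSE,none,congruent,up,left,0,0,0,0,0,0,FALSE,41000,direction_key,direction_left,580,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,11,2,experimental,ANTI,TRUE,none,congruent,up,right,0,0,0,0,0,0,FALSE,45100,direction_key,direction_right,530,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,12,2,experimental,ANTI,TRUE,valid,incongruent,up,left,0,0,0,3,0,0,TRUE,49200,direction_key,direction_left,620,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,13,2,experimental,ANTI,FALSE,invalid,incongruent,up,right,0,0,0,0,0,0,FALSE,53300,direction_key,direction_right,640,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,14,2,experimental,ANTI,TRUE,invalid,congruent,up,left,0,0,0,3,0,0,TRUE,57400,direction_key,direction_left,100,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,15,2,experimental,ANTI,TRUE,valid,congruent,up,right,0,0,0,0,0,0,FALSE,61500,direction_key,direction_right,1600,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,16,2,experimental,EV,FALSE,none,incongruent,down,left,-8,0,0,0,0,0,,65600,spacebar,spacebar,800,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,17,2,experimental,EV,TRUE,invalid,congruent,down,left,8,0,0,0,0,0,,69700,spacebar,spacebar,750,TRUE,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,18,2,experimental,AV,,,,,,,,,,,,,73800,any_key,any_key,510,,TRUE,
TOY01,1,2023-05-01 10:00:00,9999,Toy,Exp,ANTI_VEA,2,2,200,2,0,19,2,experimental,AV,,,,,,,,,,,,,77900,any_key,any_key,700,,TRUE,
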