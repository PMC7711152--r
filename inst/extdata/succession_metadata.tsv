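sample_id	substrate_bin	incubation	is_control
s001_background_i1_r1	background	1	FALSE
s002_background_i1_r2	background	1	FALSE
s003_background_i2_r1	background	2	FALSE
s004_background_i2_r2	background	2	FALSE
s005_background_i3_r1	background	3	FALSE
s006_background_i3_r2	background	3	FALSE
s007_background_i4_r1	background	4	FALSE
s008_background_i4_r2	background	4	FALSE
s009_background_i5_r1	background	5	FALSE
s010_background_i5_r2	background	5	FALSE
s011_carbonate_i1_r1	carbonate	1	FALSE
s012_carbonate_i1_r2	carbonate	1	FALSE
s013_carbonate_i2_r1	carbonate	2	FALSE
s014_carbonate_i2_r2	carbonate	2	FALSE
s015_carbonate_i3_r1	carbonate	3	FALSE
s016_carbonate_i3_r2	carbonate	3	FALSE
s017_carbonate_i4_r1	carbonate	4	FALSE
s018_carbonate_i4_r2	carbonate	4	FALSE
s019_carbonate_i5_r1	carbonate	5	FALSE
s020_carbonate_i5_r2	carbonate	5	FALSE
s021_silica_i1_r1	silica	1	FALSE
s022_silica_i1_r2	silica	1	FALSE
s023_silica_i2_r1	silica	2	FALSE
s024_silica_i2_r2	silica	2	FALSE
s025_silica_i3_r1	silica	3	FALSE
s026_silica_i3_r2	silica	3	FALSE
s027_silica_i4_r1	silica	4	FALSE
s028_silica_i4_r2	silica	4	FALSE
s029_silica_i5_r1	silica	5	FALSE
s030_silica_i5_r2	silica	5	FALSE
s031_mixed_i1_r1	mixed	1	FALSE
s032_mixed_i1_r2	mixed	1	FALSE
s033_mixed_i2_r1	mixed	2	FALSE
s034_mixed_i2_r2	mixed	2	FALSE
s035_mixed_i3_r1	mixed	3	FALSE
s036_mixed_i3_r2	mixed	3	FALSE
s037_mixed_i4_r1	mixed	4	FALSE
s038_mixed_i4_r2	mixed	4	FALSE
s039_mixed_i5_r1	mixed	5	FALSE
s040_mixed_i5_r2	mixed	5	FALSE
s041_steel_i1_r1	steel	1	FALSE
s042_steel_i1_r2	steel	1	FALSE
s043_steel_i2_r1	steel	2	FALSE
s044_steel_i2_r2	steel	2	FALSE
s045_steel_i3_r1	steel	3	FALSE
s046_steel_i3_r2	steel	3	FALSE
s047_steel_i4_r1	steel	4	FALSE
s048_steel_i4_r2	steel	4	FALSE
s049_steel_i5_r1	steel	5	FALSE
s050_steel_i5_r2	steel	5	FALSE
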