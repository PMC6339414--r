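root_id	group
116	seen by professional allied to medicine
13	physical examination finding
1123	activity exercise pattern
1121	ability to move
1124	activity of daily living
1125	eating feeding drinking ability
115	social and personal history finding
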