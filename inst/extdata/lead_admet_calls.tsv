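compound_id	HIA	Caco2	CYP1A2	CYP2C9	CYP2D6	CYP2C19	CYP3A4
Isorhamnetin	+0.9783	+0.8866	+0.9218	+0.7560	-0.6993	+0.8648	+0.7348
Kaempferide	+0.9783	+0.8866	+0.9218	+0.7560	-0.6993	+0.8648	+0.7348
Isoliquiritigenin	+0.9894	+0.8867	+0.9350	+0.8949	-0.9231	+0.8994	+0.7959
Apigenin	+0.9887	+0.8541	+0.9222	+0.7746	-0.9231	+0.7043	+0.9580
Liquiritigenin	+0.9915	+0.7142	+0.8739	+0.9352	-0.8850	+0.8456	+0.5207
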