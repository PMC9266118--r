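((EC1|unwounded:2,(EC2|unwounded:1,EC9|wounded:1):1):6,(((EC3|unwounded:1,EC10|wounded:1):2,(EC4|unwounded:1,EC11|wounded:1):2):4,(((EC7|unwounded:1,EC15|wounded:1):1,(EC8|unwounded:1,EC16|wounded:1):1):3,(EC5|unwounded:4,(EC6|unwounded:3,(EC14|wounded:2,(EC12|wounded:1,EC13|wounded:1):1):1):1):1):2):1);
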