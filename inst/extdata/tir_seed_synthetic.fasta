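>tir_synth_01 synthetic TIR-domain seed member
ISLAYVKTRSSYNCNVVDLQLMLDWMTEGYPPLLSKKEVAVNMYIELRDLMMQFILIVKVLGGVDVFLHSEATHTLNNYHLTAAQNYICDQPPVIEICADKAVCLAEKKFHLLVEKIAFGSWILAGDAVYRYAKFVVEPK
>tir_synth_02 synthetic TIR-domain seed member
IDLLYVKTRSSYNYNVVDLQLLLDWMTPGYPPLLHLVEVGMNMYIELRDLMMQQILVVKVLGGVDVFLHSEGTHTLNNYHLTAAQNYITDQIPVIEICADKLVCLAEKKFHLLVECIFFGSWILAGDAAYRYAKFVVEPK
>tir_synth_03 synthetic TIR-domain seed member
RSLAYAKTRSSYFVNVVDSQLMLDWMTEGLNPLLSSKEVAVNMYIELRDLMMQFILIVKVLGGVDVFLHSELTHTGNNAHDTAAQNYICDQPPVIEICADKAVCLAKKKAVLLVEKIAFGSWILALSSNYRPAKLVVEPK
>tir_synth_04 synthetic TIR-domain seed member
ISEAYVKTRSSYNCNVGDLQLMLDWGTEGYSPLLSKKEVAVNMYIELRDLGMQFILIVRVLVGVDVYLHSEATCTLENYHLTVAQNYICVQEPVIEICADKAVSLAELKFHLLVEKIADFSWILAGDAVAHYSKFVVELK
>tir_synth_05 synthetic TIR-domain seed member
ISLAYVKDRKCYNCNVVDLQLMQDNMTEGYPPLLSKKFVAVNMYIELRDLMLQFILIVKVLGGVDYFLHSEATHTLNNYHLTAAQNYICDQPPVIEYCAGKTVCLAEKKFHLGVEKIAFGSDILAGDAVYIYAKFVVTLK
>tir_synth_06 synthetic TIR-domain seed member
ISLAVVKVRSSYNTNVVDLCLMLDWMTEGYPNLLSKKEWAVNMYIELRDLMMQFIAIVKVQGGVPVFLHSEATHTLNSYHLHAAQNYICDKPPVIEICKVAAVCLAVQKFHCLVEKIAFGSWILAGDIVYRYSKFVVEPT
>tir_synth_07 synthetic TIR-domain seed member
TSLAYVSTRSSYNCNGVDLQLRLDWMLEGYPPSLDKKEVGVNMYIELRDLMMQFILIVKVLGQRDVFLHSEATHTLDKYHLTAAQNSICDEPPQIEICADKAVCLAELKFPLLVEKIAFGSPILCGDAVYIYAKFVVEPR
>tir_synth_08 synthetic TIR-domain seed member
ILLAYVLTRRSYNCNLADLQLMPDIATETYPPILAKKEVAVLMYIELRDLLMEFILIVKVLMGVDVFLHFEATHTLNNYHQTAGQNYICDQPPVIEICAKKAVCLAEKKCHLLVEKIAFGSWILAGDAVYRYAKFVVEPK
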